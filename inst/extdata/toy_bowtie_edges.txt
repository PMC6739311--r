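# toy bow-tie network: 3-cycle CORE {0,1,2}, IN feeder 3, OUT node 4,
# tube node 5, disconnected node 6 (node 6 appears via its own comment
# line only in documentation; unlinked nodes are absent from edge lists)
0 1
1 2
2 0
3 0
2 4
3 5
5 4
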