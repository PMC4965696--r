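# Demo analysis: up- and down-regulation indicator matrices on a
# 40-gene synthetic network, combined with OR.
network=network.tsv
matrix=UP=matrix-up.tsv,DOWN=matrix-down.tsv
formula=UP OR DOWN
strategy=INES
algorithm=greedy
K=2
L=20%
gold=gold.txt
seed=1
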