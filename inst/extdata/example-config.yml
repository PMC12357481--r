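# Example trapsim configuration: the standard invasion scenario with a
# deleterious TE. Missing keys take the package defaults.
N: 1000
u: 0.1
x: 0.01
generations: 2000
n0: 100
bias0: 0
replicates: 10
seed: 1
chromosomes: [10, 10, 10, 10, 10]   # Mbp
clusters: [300, 300, 300, 300, 300] # kb, one per chromosome (f = 0.03)
rr: [4, 4, 4, 4, 4]                 # cM/Mbp
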