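# Synthetic WT-versus-knockdown demonstration configuration.
# One 4-Mb chromosome simulated at 2-kb bins with planted TAD borders,
# chromatin loops and A/B compartments; two scripted knockdowns.
genome:
  chr1: 4000000
resolution: 2000
depth: 4000000
seeds:
  simulate: 101
  downsample: 202
  expression: 303
  permutation: 404
borders:
  - {chrom: chr1, pos: 250000,  depth: 3}
  - {chrom: chr1, pos: 560000,  depth: 3}
  - {chrom: chr1, pos: 875000,  depth: 3}
  - {chrom: chr1, pos: 1190000, depth: 3}
  - {chrom: chr1, pos: 1505000, depth: 3}
  - {chrom: chr1, pos: 1820000, depth: 3}
  - {chrom: chr1, pos: 2135000, depth: 3}
  - {chrom: chr1, pos: 2450000, depth: 3}
  - {chrom: chr1, pos: 2765000, depth: 3}
  - {chrom: chr1, pos: 3080000, depth: 3}
  - {chrom: chr1, pos: 3395000, depth: 3}
  - {chrom: chr1, pos: 3710000, depth: 3}
# loop anchors sit inside one compartment block each, away from the
# diagonal by more than the donut window
loops:
  - {chrom: chr1, pos1: 290000,  pos2: 390000,  enrichment: 5}
  - {chrom: chr1, pos1: 1220000, pos2: 1340000, enrichment: 5}
  - {chrom: chr1, pos1: 1610000, pos2: 1750000, enrichment: 5}
  - {chrom: chr1, pos1: 2420000, pos2: 2570000, enrichment: 5}
compartments:
  block_size: 200000
  factor: 2
knockdowns:
  kd_single:
    - {type: delete, chrom: chr1, pos: 560000,  value: .na}
    - {type: delete, chrom: chr1, pos: 1820000, value: .na}
    - {type: shift,  chrom: chr1, pos: 1190000, value: 1500}
    - {type: shift,  chrom: chr1, pos: 2450000, value: 10000}
    - {type: delete_loop, chrom: chr1, pos: 1220000, value: .na}
  kd_double:
    - {type: delete, chrom: chr1, pos: 560000,  value: .na}
    - {type: delete, chrom: chr1, pos: 3080000, value: .na}
    - {type: shift,  chrom: chr1, pos: 1190000, value: 1500}
    - {type: weaken, chrom: chr1, pos: 2765000, value: 1.5}
    - {type: delete_loop, chrom: chr1, pos: 2420000, value: .na}
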