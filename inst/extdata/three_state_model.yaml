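# Three-state nutrient environment with two specialist phenotypes and a
# binary sensing signal. s1y/s2y are nutrient A- and B-rich states; s3y is a
# nutrient-poor state visited occasionally. Each table is keyed first by the
# conditioning state, so every inner map is one probability distribution.
spaces:
  phenotypes: [s1x, s2x]
  environments: [s1y, s2y, s3y]
  signals: [s1z, s2z]
environment:
  transition:
    s1y: {s1y: 0.70, s2y: 0.25, s3y: 0.05}
    s2y: {s1y: 0.25, s2y: 0.70, s3y: 0.05}
    s3y: {s1y: 0.25, s2y: 0.25, s3y: 0.50}
  initial: stationary
sensing:
  kernel:
    s1y: {s1z: 0.8, s2z: 0.2}
    s2y: {s1z: 0.2, s2z: 0.8}
    s3y: {s1z: 0.5, s2z: 0.5}
  initial: from_kernel
switching:
  kernel:
    s1z: {s1x: 0.95, s2x: 0.05}
    s2z: {s1x: 0.05, s2x: 0.95}
  initial: from_kernel
replication:
  rates_are_exponentiated: true
  table:
    s1x: {s1y: 2.24, s2y: 0.32, s3y: 0.08}
    s2x: {s1y: 0.32, s2y: 2.24, s3y: 0.08}
# e^{kmax} is pinned in the nutrient-poor state; the remaining maximum rates
# follow from requiring row-stochastic allocations (here e^{kmax} = 5.12 in
# both rich states, so the poor state receives allocation 0.5 from each
# phenotype).
decomposition:
  pin: {s3y: 0.16}
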