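# Example haplogroup trees (synthetic)

`r1b_synthetic.nwk` and `e1b1a_synthetic.nwk` are SYNTHETIC stand-ins for
the empirical R1b (6 chromosomes) and E1b1a (8 chromosomes) Y-haplogroup
phylogenies, whose per-branch SNP counts are published only as a figure.

Each file is a single seeded draw from `make_synthetic_observed()` under
the package's fitted continental regime model (`europe_regime_spec()` /
`africa_regime_spec()`), with zero-variant internal branches collapsed,
screened so that

* the R1b tree is a 6-tip star with exactly one internal branch carrying
  one SNP and uniting three chromosomes,
* the E1b1a tree has 8 tips, bifurcating except for exactly one
  trifurcation, with a mutation-clock TMRCA at least as old as the
  regime's expansion start,

and selected, among screening survivors, for the lowest best-achievable
AND against a reference library of simulated scenario means (closeness to
the generating scenario's mean statistics as tie-break). Branch lengths
are integer SNP counts; tip labels are arbitrary (`t1`, `t2`, ...) and
never affect any statistic.

These files exercise the pipeline realistically but are not sequencing
data.
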