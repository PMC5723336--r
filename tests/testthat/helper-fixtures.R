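# Small shared fixtures built in code.

# hand-made 4-leaf reference package: 2 ingroup clades of 1 leaf each would
# violate the >= 2 ingroup rule, so use 4 ingroup + 2 outgroup leaves with
# simulated sequences (seeded, so identical across test runs).
toy_refpkg <- function(seed = 101, length_aa = 120) {
  make_synthetic_refpkg("toy", n_clades = 2L, leaves_per_clade = 2L,
                        n_outgroup = 2L, length_aa = length_aa, seed = seed)
}

# tiny alignment + tree for likelihood tests
tiny_tree <- function(text = "((A:0.12,B:0.3):0.08,(C:0.25,D:0.4):0.15);") {
  read_newick_numbered(text = text)
}

tiny_alignment <- function(ntree, model, nsite = 3, seed = 5) {
  aln <- simulate_alignment_on_tree(ntree, model, nsite, seed = seed)
  aln
}
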