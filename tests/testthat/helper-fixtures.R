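# Shared fixtures: the five-taxon worked example (three sampled
# topologies with multiplicities 3/2/2, k = 7) and small builders.

fig_newick <- c(
  t1 = "(((A,B),C),(D,E));",
  t2 = "(((A,(B,C)),D),E);",
  t3 = "(((A,(B,C)),E),D);"
)

example_sample <- function() {
  parse_trees(rep(fig_newick, times = c(3, 2, 2)), burnin_fraction = 0)
}

topo <- function(newick, taxa = NULL) {
  as_topology(ape::read.tree(text = newick), taxa = taxa)
}

ekey <- function(members, taxa = LETTERS[1:5]) clade_key(members, taxa)

# a sample with split AB|CD assemblable from observed clades but never
# observed as a split (the CCD0-vs-CCD1 divergence example)
split_expansion_sample <- function() {
  parse_trees(c("(((A,B),C),D);", "(((C,D),A),B);"), burnin_fraction = 0)
}

# canonical topology key (over sorted taxa) of the first tree in a
# newick string/file, robust to the tip order of the serialization
canon_key <- function(source) {
  t <- parse_trees(source, burnin_fraction = 0)$topologies[[1]]
  ccdtree:::remap_topology(t, sort(t$taxa))$key
}

random_fixture_sample <- function(n, pool = 4, max_mult = 3) {
  tops <- replicate(pool, yule_topology(n), simplify = FALSE)
  tree_sample(tops, multiplicity = sample.int(max_mult, pool, replace = TRUE))
}
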