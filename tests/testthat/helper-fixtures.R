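# Small hand-built trees used across the suite.

tree3 <- function() parse_newick("((B:1,C:1):1,A:2);")  # n=3, s=5, t=2

cherry_tree <- function(t = 1) {
  parse_newick(sprintf("(A:%.10g,B:%.10g);", t, t))
}

# one moderately large simulated tree, reproducible
sim_tree <- function(lambda, mu, age, seed) {
  out <- simulate_crown_tree(bd_params(lambda, mu), age, seed = seed)
  out$reconstructed_tree
}
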