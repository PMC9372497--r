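# In-code fixtures shared across test files.

# reduced-scale planted simulation (2 x 8 subjects x 24 ROIs, t = 60)
small_sim <- function(seed, effect = 0.4, nSubjects = 8L, nRois = 24L,
                      nTime = 60L, ...) {
  d <- plantedDesign(nSubjects = nSubjects, nRois = nRois, nTime = nTime,
                     effect = effect, seed = seed, ...)
  sim <- generatePlanted(d)
  stack <- buildStack(sim$series, combineInstances(sim$instances))
  list(sim = sim, stack = stack, design = d)
}

# a small hand-built instance with controllable lobes
toy_instance <- function(n = 5L, lobes = rep("frontal", n), atlas = "toy",
                         concept = "FPN") {
  NetworkInstance(concept, atlas, data.frame(
    roi_id = sprintf("t%02d", seq_len(n)),
    name = sprintf("toy %d", seq_len(n)),
    x = seq_len(n) * 2, y = -seq_len(n) * 3, z = seq_len(n),
    lobe = lobes, network = concept, atlas = atlas,
    stringsAsFactors = FALSE))
}

# BinaryGraph from a 0/1 matrix given as upper-triangle edge pairs
graph_from_edges <- function(n, edges) {
  A <- matrix(FALSE, n, n)
  for (e in edges) { A[e[1], e[2]] <- TRUE; A[e[2], e[1]] <- TRUE }
  BinaryGraph(sprintf("n%02d", seq_len(n)), A)
}

random_graph <- function(n, p = 0.4) {
  A <- matrix(runif(n * n) < p, n, n)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  A <- A | t(A)
  BinaryGraph(sprintf("n%02d", seq_len(n)), A)
}
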