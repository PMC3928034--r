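# Shared fixtures: a small synthetic locus so per-test simulation stays fast.

tiny_params <- function(seed = 1, ...) {
  args <- list(
    locus_length = 3e6, mean_fragment_length = 2000,
    n_vk_functional = 40, n_vk_pseudo = 20,
    library_size = 3e5, seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_params, args)
}

# a hand-built 4-fragment map on chrT: [1,100] [101,300] [301,600] [601,1000]
toy_map <- function() {
  gr <- GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(start = c(1, 101, 301, 601),
                             end = c(100, 300, 600, 1000))
  )
  kappa3C:::new_fragment_map(gr)
}

toy_profile <- function(freq, viewpoint = "vp", condition = "WT") {
  kappa3C:::new_normalized_profile(viewpoint, condition, freq,
                                   replicates = 1L)
}

toy_counts <- function(counts, library_size = sum(counts),
                       viewpoint = "vp", condition = "WT", replicate = 1L) {
  kappa3C:::new_count_profile(viewpoint, condition, replicate, counts,
                              library_size)
}

# focusing matrix helper: constant value per viewpoint row
flat_focusing <- function(value, conditions = 5) {
  m <- matrix(value, nrow = 3, ncol = conditions)
  rownames(m) <- c("Sis", "iEk", "3pEk")
  m
}
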