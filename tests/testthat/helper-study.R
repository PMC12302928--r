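# small, fully observed synthetic studies used by most module tests
smallStudy <- function(seed = 1, ...) {
  defaults <- list(n_metabolites = 40L, n_vocs = 30L, missing_rate = 0,
                   lod_quantile = 0, seed = seed)
  args <- modifyList(defaults, list(...))
  generateStudy(do.call(synthConfig, args))
}

# a plain fully observed samples x features matrix with group labels
randomXY <- function(seed, n = 9, p = 30, groups = c(4, 5)) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0("f", seq_len(p))))
  y <- rep(c("A", "B"), groups)
  list(x = x, y = y)
}
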