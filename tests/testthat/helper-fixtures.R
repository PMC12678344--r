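# Shared in-code fixtures; everything is generated, nothing is stored.

# minimal quadrat table: one plot, configurable species x quadrat layout
make_quadrats <- function(species, abundance, cover = abundance,
                          quadrat = rep("Q1", length(species)),
                          plot_id = "A-1", land_type = "A") {
  tibble::tibble(
    plot_id = plot_id, land_type = land_type, quadrat_id = quadrat,
    species = species, abundance = abundance, height = 10,
    cover = cover, present = TRUE
  )
}

# a random multi-quadrat community for property tests
random_community <- function(n_species = 5, n_quadrats = 4) {
  sp <- paste0("sp", seq_len(n_species))
  do.call(rbind, lapply(seq_len(n_quadrats), function(q) {
    n <- rpois(n_species, 4)
    keep <- n > 0
    if (!any(keep)) keep[1] <- n[1] <- 1
    make_quadrats(sp[keep], n[keep], cover = runif(sum(keep), 0.5, 30),
                  quadrat = rep(paste0("Q", q), sum(keep)))
  }))
}

# small fast settings for driver-analysis tests
fast_rf <- function(seed, n_permutations = 50, mtry_grid = 3:6,
                    n_trees = 150) {
  rf_config(mtry_grid = mtry_grid, n_trees = n_trees,
            n_permutations = n_permutations, seed = seed)
}

# literal three-loop evaluation of the grey relational coefficient,
# independent of the vectorized implementation
gra_oracle <- function(x, reference, rho = 0.5) {
  m <- nrow(x); n <- ncol(x)
  delta <- matrix(NA_real_, m, n)
  for (p in seq_len(m)) for (h in seq_len(n)) {
    delta[p, h] <- abs(reference[h] - x[p, h])
  }
  dmin <- Inf; dmax <- -Inf
  for (p in seq_len(m)) for (h in seq_len(n)) {
    if (delta[p, h] < dmin) dmin <- delta[p, h]
    if (delta[p, h] > dmax) dmax <- delta[p, h]
  }
  xi <- matrix(NA_real_, m, n)
  for (p in seq_len(m)) for (h in seq_len(n)) {
    xi[p, h] <- if (dmax == 0) 1 else
      (dmin + rho * dmax) / (delta[p, h] + rho * dmax)
  }
  dimnames(xi) <- dimnames(x)
  xi
}
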