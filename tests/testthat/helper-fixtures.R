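# Shared fixtures, built in code at test time.

# Constant-accumulation chronology: exactly `acc` yr/cm (zero-variance gamma).
const_chron <- function(acc = 10, n_sections = 20, thickness = 5, seed = 1,
                        top_age = 2015) {
  simulate_chronology(n_sections, thickness, acc, acc_shape = 1e9,
                      memory = 0, top_age = top_age, seed = seed)
}

# Hand-built age-depth ensemble with identical linear members (10 yr/cm by
# default): lets flux/interp tests control SR exactly.
linear_ensemble <- function(acc = 10, depth_max = 100, n_members = 5,
                            collection_year = 2015) {
  depth <- seq(0, depth_max, by = 10)
  ages <- matrix(rep(depth * acc, each = n_members), n_members)
  structure(list(depth = depth, ages = ages, w = rep(0.5, n_members),
                 collection_year = collection_year,
                 diagnostics = list(mode = "fixture"),
                 settings = list()),
            class = "age_depth_ensemble")
}

fast_settings <- function(...) {
  age_model_settings(n_iter = 2000, burn_in = 500, n_members = 300, ...)
}

# Independent brute-force flux oracle: scalar loops, no shared code with
# compute_fluxes.
brute_force_fluxes <- function(depth, TOC, TIC, density, ens) {
  n <- length(depth)
  M <- nrow(ens$ages)
  bounds <- c(depth[1], (depth[-1] + depth[-n]) / 2, depth[n])
  toc_f <- l_f <- matrix(NA_real_, M, n)
  for (m in seq_len(M)) {
    age_at <- function(dd) approx(ens$depth, ens$ages[m, ], xout = dd)$y
    for (j in seq_len(n)) {
      sr <- (bounds[j + 1] - bounds[j]) / (age_at(bounds[j + 1]) - age_at(bounds[j]))
      toc_f[m, j] <- density[j] * sr * (TOC[j] / 100) * 1e4
      l_f[m, j] <- density[j] * sr * ((100 - TOC[j] - TIC[j]) / 100) * 1e4
    }
  }
  list(toc = toc_f, l = l_f)
}
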