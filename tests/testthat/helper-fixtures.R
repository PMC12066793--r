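# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

small_config <- function(...) {
  county_config(n_rows = 24, n_cols = 24, n_years = 6, seed = 42,
                corr_length = 4, mask_fraction = 0.05, wind_n_obs = 30, ...)
}

small_series <- function() cached("small_series", {
  generate_annual_series(small_config())
})

small_es <- function() cached("small_es", {
  suppressWarnings(lapply(small_series(), quantify_all))
})

flat_grid <- function(v, nr = 8, nc = 8, cell = 1000, categorical = FALSE) {
  raster_grid(matrix(v, nr, nc), cell_size = cell, categorical = categorical)
}

# synthetic es_layers list with service rasters supplied directly
fake_es_list <- function(service_mats, cell = 1000) {
  n_years <- length(service_mats[[1]])
  lapply(seq_len(n_years) - 1L, function(y) {
    services <- lapply(service_mats, function(mats)
      raster_grid(mats[[y + 1]], cell_size = cell))
    structure(list(year = y, services = services), class = "es_layers")
  })
}

# ---- brute-force Shapley enumeration oracle --------------------------------
# Exact Shapley values for an xgboost regression ensemble, with the
# tree-traversal (cover-weighted) conditional expectation value function:
# features outside the coalition S descend both children weighted by cover.

tree_expectation <- function(tree, node_id, x, in_S) {
  node <- tree[tree$ID == node_id, ]
  if (node$Feature == "Leaf") return(node$Gain)  # leaf value is in Gain
  if (node$Feature %in% in_S) {
    branch <- if (x[[node$Feature]] < node$Split) node$Yes else node$No
    return(tree_expectation(tree, branch, x, in_S))
  }
  cy <- tree$Cover[tree$ID == node$Yes]
  cn <- tree$Cover[tree$ID == node$No]
  (cy * tree_expectation(tree, node$Yes, x, in_S) +
     cn * tree_expectation(tree, node$No, x, in_S)) / (cy + cn)
}

ensemble_value <- function(trees, x, in_S) {
  sum(vapply(trees, function(tr)
    tree_expectation(tr, tr$ID[1], x, in_S), numeric(1)))
}

shapley_enumerate <- function(model, row) {
  dump <- xgboost::xgb.model.dt.tree(model = model$booster)
  dump <- as.data.frame(dump)
  trees <- split(dump, dump$Tree)
  feats <- model$features
  k <- length(feats)
  phi <- setNames(numeric(k), feats)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  for (j in seq_len(k)) {
    for (si in seq_len(nrow(subsets))) {
      inc <- unlist(subsets[si, ])
      if (inc[j]) next
      S <- feats[inc]
      s <- length(S)
      w <- factorial(s) * factorial(k - s - 1) / factorial(k)
      phi[j] <- phi[j] +
        w * (ensemble_value(trees, row, c(S, feats[j])) -
               ensemble_value(trees, row, S))
    }
  }
  phi
}
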