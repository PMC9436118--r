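# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately naive (double loops, dense searches) and never call the code
# paths they check.

toy_spec <- function(noise_sd = 0) {
  hinge_spec(n_per_domain = 25, linker = 5, noise_sd = noise_sd)
}

# closed enough for inter-domain contacts
toy_closed <- function(angle = 150, ...) {
  hinge_model(toy_spec(), angle, model_id = paste0("closed", angle), ...)
}

toy_open <- function(angle = 120, ...) {
  hinge_model(toy_spec(), angle, model_id = paste0("open", angle), ...)
}

# O(atoms^2) contact oracle: minimum heavy-atom distance per residue pair
brute_contact_set <- function(model, window, cutoff = 4, exclusion = 4,
                              mutate = "both") {
  at <- model$atoms
  n <- n_residues(model)
  win <- window[1]:window[2]
  hits_i <- integer(0); hits_j <- integer(0)
  for (i in win) {
    ai <- at[at$res_index == i, c("x", "y", "z"), drop = FALSE]
    for (j in seq_len(n)) {
      if (min(abs(j - win)) <= exclusion) next  # window & neighbors
      aj <- at[at$res_index == j, c("x", "y", "z"), drop = FALSE]
      dmin <- Inf
      for (p in seq_len(nrow(ai))) for (q in seq_len(nrow(aj))) {
        dmin <- min(dmin, sqrt(sum((ai[p, ] - aj[q, ])^2)))
      }
      if (dmin <= cutoff) {
        hits_i <- c(hits_i, i); hits_j <- c(hits_j, j)
      }
    }
  }
  switch(mutate,
         both = sort(unique(c(hits_i, hits_j))),
         window = sort(unique(hits_i)),
         partners = sort(unique(hits_j)))
}

# dense-seed TM oracle: superpositions seeded from the whole chain and
# from every 6- and 15-residue fragment, refined at several distance
# cutoffs, max over everything
brute_tm <- function(model, reference, corr = NULL) {
  if (is.null(corr)) corr <- correspondence(model, reference)
  X <- ca_coords(model)[corr$i, , drop = FALSE]
  Y <- ca_coords(reference)[corr$j, , drop = FALSE]
  L <- n_residues(reference)
  d0 <- if (L <= 21) 0.5 else max(1.24 * (L - 15)^(1 / 3) - 1.8, 0.5)
  score <- function(sel) {
    f <- alamsa:::kabsch(X[sel, , drop = FALSE], Y[sel, , drop = FALSE])
    Xr <- sweep(X %*% f$rotation, 2, f$translation, `+`)
    d <- sqrt(rowSums((Xr - Y)^2))
    list(tm = sum(1 / (1 + (d / d0)^2)) / L, d = d)
  }
  seeds <- list(seq_len(nrow(X)))
  for (fl in c(6L, 15L)) {
    for (st in seq_len(nrow(X) - fl + 1L)) {
      seeds <- c(seeds, list(st:(st + fl - 1L)))
    }
  }
  best <- 0
  for (sd0 in seeds) {
    for (cut0 in c(max(d0 + 1, 3.5), max(d0 + 2.5, 5), 8)) {
      sel <- sd0
      for (rep_ in 1:50) {
        r <- tryCatch(score(sel), error = function(e) NULL)
        if (is.null(r)) break
        best <- max(best, r$tm)
        cut <- cut0
        new_sel <- which(r$d < cut)
        while (length(new_sel) < 3L) {
          cut <- cut + 0.5
          new_sel <- which(r$d < cut)
        }
        if (identical(new_sel, sel)) break
        sel <- new_sel
      }
    }
  }
  best
}

random_rigid_motion <- function(seed = 1) {
  set.seed(seed)
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- alamsa:::rot_mat(ax, stats::runif(1, 10, 170))
  list(rotation = R, translation = stats::rnorm(3, 0, 20))
}

# tiny hand-built structure: one atom per residue at given coordinates
point_model <- function(coords, resid = "GLY", plddt = NULL,
                        model_id = "points") {
  n <- nrow(coords)
  atoms <- data.frame(res_index = seq_len(n), resno = seq_len(n),
                      resid = resid, elety = "CA",
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      stringsAsFactors = FALSE)
  structure_model(atoms, plddt = plddt, model_id = model_id)
}

with_plddt <- function(model, plddt) {
  model$residues$plddt <- plddt
  model
}
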