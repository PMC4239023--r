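# Independent oracles and small fixture builders shared across tests.

# Pure-R flood-fill connected-component labelling (the oracle for
# label_components). Returns an integer label matrix.
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 4)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(i, j), 1)
    lab[i, j] <- cur
    while (nrow(queue) > 0) {
      p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      for (k in seq_len(nrow(nbr))) {
        r <- p[1] + nbr[k, 1]; c <- p[2] + nbr[k, 2]
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue <- rbind(queue, c(r, c))
        }
      }
    }
  }
  lab
}

# Do two labelings induce the same partition of the foreground pixels?
same_partition <- function(a, b) {
  fa <- a[a > 0]; fb <- b[b > 0]
  if (length(fa) != length(fb)) return(FALSE)
  identical(as.integer(interaction(fa, drop = TRUE)),
            as.integer(interaction(fb, drop = TRUE))) ||
    all(tapply(fb, fa, function(v) length(unique(v))) == 1) &&
    all(tapply(fa, fb, function(v) length(unique(v))) == 1)
}

# Brute-force one-sided two-sample KS statistic sup_t (F_y(t) - F_x(t)).
ecdf_sweep_stat <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(vapply(grid, function(t) mean(y <= t) - mean(x <= t), numeric(1)))
}

# Hand-built registry with exact fields (bypasses the sampler).
make_registry <- function(n_true, density, x, y, region = "continent",
                          n_vhr = n_true, vhr_cv = 0, geometry = c(64, 64)) {
  df <- data.frame(
    colony_id = sprintf("t-%03d", seq_along(n_true)),
    region = region, x = x, y = y,
    n_true = as.integer(n_true), n_vhr = as.integer(n_vhr),
    vhr_cv = vhr_cv, guano_area_true = n_true / density,
    excluded = FALSE, stringsAsFactors = FALSE)
  class(df) <- c("colony_registry", "data.frame")
  attr(df, "geometry") <- geometry
  df
}

# Abundance fit object with prescribed parameters (for envelope tests).
manual_abundance_fit <- function(beta, se = 0, tau = 0, region = "continent") {
  structure(list(region = region, beta = beta, se = se,
                 tau_log_resid = tau, n = NA_integer_),
            class = "abundance_model_fit")
}

# A small two-class spectral library with controllable separation:
# background mean is `sep` pooled standard deviations from guano.
toy_library <- function(sep = 10, sd = 0.01) {
  delta <- sep * sd / sqrt(6)
  spectral_library(list(
    guano = list(mean = rep(0.40, 6), cov = diag(sd^2, 6)),
    rock  = list(mean = rep(0.40 + delta, 6), cov = diag(sd^2, 6))
  ))
}
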