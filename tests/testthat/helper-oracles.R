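# Independent brute-force oracles used to validate the package's
# implementations.  These deliberately use naive enumeration/loops and no
# code paths from the package internals.

# AUC by enumerating all event/non-event pairs; ties count 1/2.
oracle_auc <- function(scores, labels) {
  ev <- scores[labels == 1]
  ne <- scores[labels == 0]
  tot <- 0
  for (a in ev) for (b in ne)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ev) * length(ne))
}

# Bernoulli log-likelihood evaluated term by term from the printed logistic.
oracle_loglik <- function(D, y, D50, gamma, eps = 1e-12) {
  s <- 4 * gamma / D50
  tot <- 0
  for (i in seq_along(D)) {
    p <- 1 / (1 + exp(s * (D50 - D[i])))
    p <- min(max(p, eps), 1 - eps)
    tot <- tot + y[i] * log(p) + (1 - y[i]) * log(1 - p)
  }
  tot
}

# Exhaustive grid-search maximizer of the NTCP likelihood.
oracle_grid_fit <- function(D, y, D50_range = c(0.5, 1.5),
                            gamma_range = c(0.05, 3), n_grid = 200) {
  d50s <- seq(D50_range[1], D50_range[2], length.out = n_grid)
  gams <- seq(gamma_range[1], gamma_range[2], length.out = n_grid)
  best <- c(ll = -Inf, D50 = NA, gamma = NA)
  for (d50 in d50s) {
    s <- 4 * gams / d50
    # vectorized over the gamma axis only; each entry is the plain formula
    ll <- vapply(s, function(si) {
      p <- 1 / (1 + exp(si * (d50 - D)))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      sum(y * log(p) + (1 - y) * log(1 - p))
    }, numeric(1))
    k <- which.max(ll)
    if (ll[k] > best["ll"]) best <- c(ll = ll[k], D50 = d50, gamma = gams[k])
  }
  list(ll = best[["ll"]], D50 = best[["D50"]], gamma = best[["gamma"]],
       step_D50 = diff(d50s[1:2]), step_gamma = diff(gams[1:2]))
}

# Voxel-counting metric oracles on plain arrays (mask: logical array).
oracle_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(a)) {
    na <- na + a[i]; nb <- nb + b[i]
    inter <- inter + (a[i] && b[i])
  }
  2 * inter / (na + nb)
}

oracle_mean_dose <- function(dose, mask) {
  tot <- 0; n <- 0
  for (i in seq_along(mask)) if (mask[i]) { tot <- tot + dose[i]; n <- n + 1 }
  tot / n
}

oracle_vxgy <- function(dose, mask, x) {
  hit <- 0; n <- 0
  for (i in seq_along(mask)) if (mask[i]) {
    n <- n + 1
    if (dose[i] >= x) hit <- hit + 1
  }
  100 * hit / n
}

# Boundary voxel faces by explicit neighbour checks (grid edge = background);
# returns face-center coordinates (mm) and areas (mm^2).
oracle_faces <- function(mask, spacing, origin = c(0, 0, 0)) {
  dm <- dim(mask)
  centers <- list(); areas <- c()
  nb <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
              c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (!mask[i, j, k]) next
    for (q in 1:6) {
      ii <- i + nb[q, 1]; jj <- j + nb[q, 2]; kk <- k + nb[q, 3]
      outside <- ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] ||
        kk < 1 || kk > dm[3]
      if (outside || !mask[ii, jj, kk]) {
        ctr <- origin + (c(i, j, k) - 1) * spacing + nb[q, ] * spacing / 2
        centers[[length(centers) + 1L]] <- ctr
        axis <- which(nb[q, ] != 0)
        areas <- c(areas, prod(spacing[-axis]))
      }
    }
  }
  list(centers = do.call(rbind, centers), areas = areas)
}

oracle_surface_dice <- function(a, b, spacing, tol, origin = c(0, 0, 0)) {
  fa <- oracle_faces(a, spacing, origin)
  fb <- oracle_faces(b, spacing, origin)
  min_d <- function(p, qs)
    min(sqrt((qs[, 1] - p[1])^2 + (qs[, 2] - p[2])^2 + (qs[, 3] - p[3])^2))
  da <- apply(fa$centers, 1, min_d, qs = fb$centers)
  db <- apply(fb$centers, 1, min_d, qs = fa$centers)
  tol <- tol + 1e-9
  (sum(fa$areas[da <= tol]) + sum(fb$areas[db <= tol])) /
    (sum(fa$areas) + sum(fb$areas))
}

# Closed-form volume of the intersection lens of two spheres with radii
# r1, r2 and center distance d.
sphere_lens_volume <- function(r1, r2, d) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * min(r1, r2)^3)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
}

sphere_volume <- function(r) 4 / 3 * pi * r^3

# A small normalized synthetic cohort for engine tests.
make_test_cohort <- function(n = 200, rank_correlation = 0.9, seed = 42,
                             ...) {
  normalize_cohort(generate_cohort(n, rank_correlation = rank_correlation,
                                   seed = seed, ...))
}

random_mask <- function(dm = c(8, 8, 8), p = 0.35) {
  array(runif(prod(dm)) < p, dm)
}
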