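# Brute-force oracles for the texture features: every matrix is built by
# explicit enumeration (voxel pairs, maximal runs, flood-filled zones,
# per-voxel neighbourhoods) and every feature formula is computed with
# plain loops, independently of the package implementation.

oracle_dirs13 <- local({
  d <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  d <- d[rowSums(abs(d)) > 0, ]
  d[apply(d, 1, function(v) { nz <- v[v != 0]; nz[1] > 0 }), ]
})

in_grid <- function(p, dm) all(p >= 1) && all(p <= dm)

# --- GLCM: enumerate every in-mask voxel pair per offset ------------------
oracle_glcm_matrix <- function(levels, dirs = oracle_dirs13) {
  dm <- dim(levels)
  G <- max(levels)
  M <- matrix(0, G, G)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    li <- levels[x, y, z]
    if (li == 0) next
    for (r in seq_len(nrow(dirs))) {
      q <- c(x, y, z) + dirs[r, ]
      if (!in_grid(q, dm)) next
      lj <- levels[q[1], q[2], q[3]]
      if (lj == 0) next
      M[li, lj] <- M[li, lj] + 1
      M[lj, li] <- M[lj, li] + 1
    }
  }
  M / sum(M)
}

oracle_glcom_features <- function(levels, G, dirs = oracle_dirs13) {
  p0 <- oracle_glcm_matrix(levels, dirs)
  p <- matrix(0, G, G)
  p[1:nrow(p0), 1:ncol(p0)] <- p0
  f <- c()
  px <- rowSums(p)
  mu <- 0
  for (i in 1:G) mu <- mu + i * px[i]
  sig2 <- 0
  for (i in 1:G) sig2 <- sig2 + (i - mu)^2 * px[i]
  acc <- function(fun) {
    s <- 0
    for (i in 1:G) for (j in 1:G) if (p[i, j] > 0) s <- s + fun(i, j)
    s
  }
  f["GLCOM_energy"] <- acc(function(i, j) p[i, j]^2)
  f["GLCOM_entropy"] <- -acc(function(i, j) p[i, j] * log2(p[i, j]))
  f["GLCOM_contrast"] <- acc(function(i, j) (i - j)^2 * p[i, j])
  f["GLCOM_dissimilarity"] <- acc(function(i, j) abs(i - j) * p[i, j])
  f["GLCOM_homogeneity"] <- acc(function(i, j) p[i, j] / (1 + abs(i - j)))
  f["GLCOM_inverse_difference_moment"] <-
    acc(function(i, j) p[i, j] / (1 + (i - j)^2))
  f["GLCOM_inverse_difference_moment_normalized"] <-
    acc(function(i, j) p[i, j] / (1 + ((i - j) / G)^2))
  f["GLCOM_inverse_difference_normalized"] <-
    acc(function(i, j) p[i, j] / (1 + abs(i - j) / G))
  f["GLCOM_correlation"] <- if (sig2 > 1e-12)
    (acc(function(i, j) i * j * p[i, j]) - mu^2) / sig2 else 0
  f["GLCOM_autocorrelation"] <- acc(function(i, j) i * j * p[i, j])
  f["GLCOM_cluster_tendency"] <-
    acc(function(i, j) (i + j - 2 * mu)^2 * p[i, j])
  f["GLCOM_cluster_shade"] <-
    acc(function(i, j) (i + j - 2 * mu)^3 * p[i, j])
  f["GLCOM_cluster_prominence"] <-
    acc(function(i, j) (i + j - 2 * mu)^4 * p[i, j])
  f["GLCOM_maximum_probability"] <- max(p)
  f["GLCOM_joint_average"] <- acc(function(i, j) i * p[i, j])
  f["GLCOM_joint_variance"] <- acc(function(i, j) (i - mu)^2 * p[i, j])
  psum <- rep(0, 2 * G)
  pdif <- rep(0, G)
  for (i in 1:G) for (j in 1:G) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  sa <- sum((1:(2 * G)) * psum)
  da <- sum((0:(G - 1)) * pdif)
  f["GLCOM_sum_average"] <- sa
  f["GLCOM_sum_variance"] <- sum(((1:(2 * G)) - sa)^2 * psum)
  f["GLCOM_sum_entropy"] <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  f["GLCOM_difference_average"] <- da
  f["GLCOM_difference_variance"] <- sum(((0:(G - 1)) - da)^2 * pdif)
  f["GLCOM_difference_entropy"] <-
    -sum(pdif[pdif > 0] * log2(pdif[pdif > 0]))
  f
}

# --- GLRLM: list every maximal run explicitly -----------------------------
oracle_runs <- function(levels, dirs = oracle_dirs13) {
  dm <- dim(levels)
  runs <- list()
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      li <- levels[x, y, z]
      if (li == 0) next
      prev <- c(x, y, z) - d
      if (in_grid(prev, dm) && levels[prev[1], prev[2], prev[3]] == li)
        next
      len <- 1
      q <- c(x, y, z) + d
      while (in_grid(q, dm) && levels[q[1], q[2], q[3]] == li) {
        len <- len + 1
        q <- q + d
      }
      runs[[length(runs) + 1]] <- c(level = li, length = len)
    }
  }
  do.call(rbind, runs)
}

oracle_glrlm_features <- function(levels, dirs = oracle_dirs13) {
  runs <- oracle_runs(levels, dirs)
  nr <- nrow(runs)
  np <- sum(levels > 0) * nrow(dirs)
  i <- runs[, "level"]
  j <- runs[, "length"]
  c(GLRLM_short_run_emphasis = sum(1 / j^2) / nr,
    GLRLM_long_run_emphasis = sum(j^2) / nr,
    GLRLM_grey_level_nonuniformity = sum(table(i)^2) / nr,
    GLRLM_run_length_nonuniformity = sum(table(j)^2) / nr,
    GLRLM_run_percentage = nr / np,
    GLRLM_low_grey_level_run_emphasis = sum(1 / i^2) / nr,
    GLRLM_high_grey_level_run_emphasis = sum(i^2) / nr,
    GLRLM_short_run_low_grey_level_emphasis = sum(1 / (i^2 * j^2)) / nr,
    GLRLM_short_run_high_grey_level_emphasis = sum(i^2 / j^2) / nr,
    GLRLM_long_run_low_grey_level_emphasis = sum(j^2 / i^2) / nr,
    GLRLM_long_run_high_grey_level_emphasis = sum(i^2 * j^2) / nr)
}

# --- GLSZM: flood-fill connected components (26-connectivity) -------------
oracle_zones <- function(levels) {
  dm <- dim(levels)
  seen <- array(FALSE, dm)
  zones <- list()
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    if (levels[x, y, z] == 0 || seen[x, y, z]) next
    li <- levels[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(nb))) {
        q <- v + nb[r, ]
        if (in_grid(q, dm) && !seen[q[1], q[2], q[3]] &&
            levels[q[1], q[2], q[3]] == li) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(level = li, size = size)
  }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(levels) {
  zs <- oracle_zones(levels)
  i <- zs[, "level"]
  s <- zs[, "size"]
  nz <- nrow(zs)
  np <- sum(levels > 0)
  c(GLSZM_small_zone_emphasis = mean(1 / s^2),
    GLSZM_large_zone_emphasis = mean(s^2),
    GLSZM_grey_level_nonuniformity = sum(table(i)^2) / nz,
    GLSZM_zone_size_nonuniformity = sum(table(s)^2) / nz,
    GLSZM_zone_percentage = nz / np,
    GLSZM_low_grey_level_zone_emphasis = mean(1 / i^2),
    GLSZM_high_grey_level_zone_emphasis = mean(i^2),
    GLSZM_small_zone_low_grey_level_emphasis = mean(1 / (s^2 * i^2)),
    GLSZM_small_zone_high_grey_level_emphasis = mean(i^2 / s^2),
    GLSZM_large_zone_low_grey_level_emphasis = mean(s^2 / i^2),
    GLSZM_large_zone_high_grey_level_emphasis = mean(s^2 * i^2),
    GLSZM_grey_level_variance = mean((i - mean(i))^2),
    GLSZM_zone_size_variance = mean((s - mean(s))^2))
}

# --- NGLDM: direct per-voxel 26-neighbourhood enumeration -----------------
oracle_ngldm_features <- function(levels, G) {
  dm <- dim(levels)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  s <- rep(0, G)
  n <- rep(0, G)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    li <- levels[x, y, z]
    if (li == 0) next
    vals <- c()
    for (r in seq_len(nrow(nb))) {
      q <- c(x, y, z) + nb[r, ]
      if (in_grid(q, dm) && levels[q[1], q[2], q[3]] > 0)
        vals <- c(vals, levels[q[1], q[2], q[3]])
    }
    if (length(vals) > 0) {
      n[li] <- n[li] + 1
      s[li] <- s[li] + abs(li - mean(vals))
    }
  }
  N <- sum(n)
  eps <- 1e-12
  p <- n / N
  act <- which(p > 0)
  ngp <- length(act)
  coarse <- 1 / (sum(p[act] * s[act]) + eps)
  contrast <- 0
  if (ngp > 1) {
    cc <- 0
    for (i in act) for (j in act) cc <- cc + p[i] * p[j] * (i - j)^2
    contrast <- cc / (ngp * (ngp - 1)) * sum(s) / N
  }
  bden <- 0
  for (i in act) for (j in act) bden <- bden + abs(i * p[i] - j * p[j])
  busy <- if (bden > 0) sum(p[act] * s[act]) / bden else 0
  compl <- 0
  for (i in act) for (j in act)
    compl <- compl + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) /
      (p[i] + p[j])
  compl <- compl / N
  stren <- 0
  for (i in act) for (j in act) stren <- stren + (p[i] + p[j]) * (i - j)^2
  stren <- stren / (sum(s) + eps)
  c(NGLDM_coarseness = coarse, NGLDM_contrast = contrast,
    NGLDM_busyness = busy, NGLDM_complexity = compl,
    NGLDM_texture_strength = stren)
}

# --- AUC oracle: tie-corrected Mann-Whitney U / (n0 n1) -------------------
oracle_auc_mw <- function(scores, labels) {
  s1 <- scores[labels == 1]
  s0 <- scores[labels == 0]
  u <- 0
  for (a in s1) for (b in s0) u <- u + (a > b) + 0.5 * (a == b)
  u / (length(s1) * length(s0))
}

# --- univariate Cox LRT oracle: hand-coded partial likelihood -------------
# Breslow tie handling; valid for the untied survival times used in tests.
oracle_cox_lrt_p <- function(x, time, event) {
  nll <- function(beta) {
    eta <- beta * x
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + eta[i] - log(sum(exp(eta[risk])))
    }
    -ll
  }
  opt <- optimize(nll, c(-50, 50))
  lr <- 2 * (nll(0) - opt$objective)
  pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
}
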