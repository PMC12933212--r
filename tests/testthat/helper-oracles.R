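# Small fixture builders and independent brute-force oracles. The oracles
# deliberately use per-subject / per-voxel loops (never the package's matrix
# paths) so they can disagree with the implementation.

toy_grid <- function(dims = c(4, 4, 4)) voxel_grid(dims)

random_masks <- function(n, grid = toy_grid(), p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      repeat {
        arr <- array(rbinom(n_voxels(grid), 1, p), grid$dims)
        if (sum(arr) >= 1) break
      }
      lesion_mask(arr, grid, sprintf("T%02d", i))
    })
  })
}

# overlap by an explicit per-voxel, per-subject loop
oracle_overlap <- function(masks) {
  V <- n_voxels(masks[[1]]$grid)
  out <- numeric(V)
  for (v in seq_len(V)) {
    for (m in masks) out[v] <- out[v] + as.numeric(m$data[v])
  }
  out
}

# group lesion proportion by loop
oracle_prop <- function(masks, members, voxels) {
  sapply(voxels, function(v) {
    cnt <- 0
    for (m in masks[members]) cnt <- cnt + as.numeric(m$data[v])
    cnt / sum(members)
  })
}

# proportional difference by loop-based counts on the exact integer lattice
# (numerator over np * nm), matching the package's tie-exact arithmetic
oracle_D <- function(masks, groups, voxels) {
  np <- sum(groups == 1)
  nm <- sum(groups == -1)
  num <- sapply(voxels, function(v) {
    cp <- 0; cm <- 0
    for (s in seq_along(masks)) {
      les <- as.numeric(masks[[s]]$data[v])
      if (groups[s] == 1) cp <- cp + les else cm <- cm + les
    }
    cp * nm - cm * np
  })
  num / (np * nm)
}

# per-voxel uncorrected two-sided permutation p by full loop over stored
# permutations of the labels
oracle_uncorrected_p <- function(masks, groups, voxels, perms) {
  D_of <- function(g) oracle_D(masks, g, voxels)
  D_obs <- D_of(groups)
  B <- ncol(perms)
  sapply(seq_along(voxels), function(j) {
    count <- 0
    for (b in seq_len(B)) {
      if (abs(D_of(perms[, b])[j]) >= abs(D_obs[j])) count <- count + 1
    }
    (1 + count) / (B + 1)
  })
}

# PLS1 with k components equals least squares restricted to the Krylov
# space span{X'y, (X'X)X'y, ...} — an independent closed-form oracle.
oracle_krylov_pls <- function(X, y, ncomp) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  y0 <- y - mean(y)
  s <- crossprod(Xc, y0)
  K <- matrix(0, ncol(X), ncomp)
  v <- s
  for (a in seq_len(ncomp)) {
    K[, a] <- v
    v <- crossprod(Xc, Xc %*% v)
  }
  Z <- Xc %*% K
  g <- qr.solve(qr(Z), y0)
  b <- drop(K %*% g)
  fitted <- drop(Z %*% g)
  list(coef = b, r2 = 1 - sum((y0 - fitted)^2) / sum(y0^2))
}

# 6-connectivity component count, for checking generated lesions are
# single connected components
oracle_n_components6 <- function(arr) {
  dims <- dim(arr)
  vox <- which(arr > 0)
  if (!length(vox)) return(0L)
  lab <- integer(length(vox))
  pos <- match(seq_len(prod(dims)), vox)  # grid index -> local index or NA
  coords <- arrayInd(vox, dims)
  ncomp <- 0L
  for (s in seq_along(vox)) {
    if (lab[s] > 0) next
    ncomp <- ncomp + 1L
    queue <- s
    lab[s] <- ncomp
    while (length(queue)) {
      cur <- queue[1]
      queue <- queue[-1]
      cc <- coords[cur, ]
      for (d in 1:3) {
        for (step in c(-1, 1)) {
          nb <- cc
          nb[d] <- nb[d] + step
          if (nb[d] < 1 || nb[d] > dims[d]) next
          lin <- nb[1] + (nb[2] - 1) * dims[1] + (nb[3] - 1) * dims[1] * dims[2]
          loc <- pos[lin]
          if (!is.na(loc) && lab[loc] == 0) {
            lab[loc] <- ncomp
            queue <- c(queue, loc)
          }
        }
      }
    }
  }
  ncomp
}

# centre-clustered cohort used by the calibration and recovery suites:
# 20^3 grid, lesions grown from centre-biased seeds
clustered_cohort <- function(n, volume_range, seed, grid_dims = c(20, 20, 20)) {
  cfg <- sim_config(grid_dims = grid_dims, n_subjects = n,
                    volume_range = volume_range, seed = seed)
  generate_lesions(cfg)
}
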