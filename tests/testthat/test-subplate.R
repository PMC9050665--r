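test_that("subplate sizing follows the one-afferent-per-slot rule", {
  s <- subplate_from_afferent_count(360000)
  expect_equal(s$shape, c(600L, 600L))
  expect_equal(s$physical_um, 30000)
  s2 <- subplate_from_afferent_count(3600)
  expect_equal(s2$shape, c(60L, 60L))
  expect_equal(s2$physical_um, 3000)
  s3 <- subplate_from_afferent_count(1)
  expect_equal(s3$shape, c(1L, 1L))
  expect_equal(s3$physical_um, 50)
  expect_equal(subplate_from_afferent_count(10)$n_padded, 6L)
  expect_error(subplate_from_afferent_count(0))
})

test_that("sorting filter matches the difference-of-Gaussians densities", {
  sc <- 100
  f <- make_sorting_filter(sc, 2 * sc, 2 * sc, rho = 0)
  ## value at the origin: centre density minus surround density
  expect_equal(f$kernel[f$c0, f$c0],
               1 / (2 * pi * sc^2) * (1 - 1 / 4))
  ## circular surround, rho = 0: rotational symmetry
  expect_lt(max(abs(f$kernel - t(f$kernel))), 1e-12)
  ## decay: beyond 4 sigma in every direction the kernel is negligible
  peak <- max(abs(f$kernel))
  expect_lt(abs(f$kernel[1L, 1L]), 1e-6 * peak)
  expect_error(make_sorting_filter(100, 100, 100, rho = 1), "rho")
  expect_error(make_sorting_filter(-1, 100, 100), "positive")
})

test_that("filter rho helper reproduces the printed normalized dot product", {
  expect_equal(filter_rho(c(1, 0), c(0, 1)), 0)
  expect_equal(filter_rho(c(1, 2), c(2, 4)), 1)
  expect_equal(filter_rho(c(1, 0), c(-1, 0)), -1)
})

test_that("retinotopic assignment preserves rank order and handles ties by arrival", {
  aff <- data.frame(eye = 1, polarity = c(1, -1, 1, -1),
                    rx = c(1, 10, 1, 10), ry = c(1, 1, 10, 10), sigma = 2)
  sp <- assign_retinotopy(aff, seed = 1L)
  expect_equal(dim(sp$occupancy), c(2L, 2L))
  ## lowest retinotopy at the top-left slot
  expect_equal(sp$afferents$rx[sp$occupancy[1L, 1L]], 1)
  expect_equal(sp$afferents$rx[sp$occupancy[2L, 1L]], 10)
  expect_equal(sp$afferents$ry[sp$occupancy[1L, 2L]], 10)

  ## distinct retinotopies: assignment independent of the arrival order
  sp2 <- assign_retinotopy(aff, seed = 99L)
  expect_identical(sp$occupancy, sp2$occupancy)

  ## two eyes with identical retinotopy: each eye wins the best slot about
  ## half of the time across seeds
  tie <- data.frame(eye = c(1, -1), polarity = 1, rx = c(0, 0), ry = c(0, 0),
                    sigma = 2)
  wins <- vapply(1:100, function(s) {
    spt <- assign_retinotopy(tie, grid_shape = c(2L, 1L), seed = s)
    tie$eye[spt$occupancy[1L, 1L]] == 1
  }, logical(1))
  expect_gt(mean(wins), 0.3)
  expect_lt(mean(wins), 0.7)

  expect_error(assign_retinotopy(aff, grid_shape = c(1L, 1L)), "fewer slots")
})

test_that("a fully segregated plate is a fixed point of the sorting step", {
  n <- 8L
  aff <- data.frame(eye = rep(c(1, -1), each = n * n / 2),
                    polarity = 1,
                    rx = seq_len(n * n), ry = 1, sigma = 2)
  sp <- structure(list(occupancy = matrix(seq_len(n * n), n, n),
                       active = matrix(TRUE, n, n),
                       afferents = aff, shape = c(n, n), pitch_um = 50),
                  class = "subplate")
  ## occupancy column-major: first half of slots (left columns) contra.
  ## Afferents may still drift within their own territory (same-value
  ## swaps), but the segregated channel map itself is a fixed point.
  f <- make_sorting_filter(100, 200, 200)
  sp1 <- sorting_step(sp, f, "eye", seed = 1L)
  eye0 <- matrix(aff$eye[sp$occupancy], n, n)
  eye1 <- matrix(aff$eye[sp1$occupancy], n, n)
  expect_identical(eye1, eye0)
})

test_that("sorting step agrees with a brute-force 9-candidate oracle", {
  ## independent oracle: replay the whole sequential pass with direct
  ## (loop-based) convolution evaluation of the swapped map at each of the
  ## 9 candidates, using the same visit order and tie rules
  naive_step <- function(sp, f, seed) {
    n <- sp$shape[1L]
    M <- matrix(sp$afferents$eye[sp$occupancy], n, n)
    occ <- sp$occupancy
    visit <- cortimap:::with_seed(sub_seed(seed, "sorting-visit"),
                                  sample.int(n * n))
    offs <- expand.grid(dx = -1:1, dy = -1:1)
    offs <- offs[order(offs$dy, offs$dx), ]
    for (a in visit) {
      s <- which(occ == a)
      i <- ((s - 1L) %% n) + 1L; j <- ((s - 1L) %/% n) + 1L
      scores <- c(); cand <- list()
      for (k in seq_len(9L)) {
        ci <- i + offs$dx[k]; cj <- j + offs$dy[k]
        if (ci < 1 || ci > n || cj < 1 || cj > n) next
        R <- brute_force_response(M, f$kernel, f$c0, i, j, ci, cj)
        scores <- c(scores, M[i, j] * R)
        cand[[length(cand) + 1L]] <- c(ci, cj)
      }
      cur <- which(vapply(cand, function(p) all(p == c(i, j)), logical(1)))
      if (scores[cur] >= max(scores) - 1e-12) next
      pick <- cand[[which(scores >= max(scores) - 1e-12)[1L]]]
      b <- occ[pick[1L], pick[2L]]
      occ[pick[1L], pick[2L]] <- a; occ[i, j] <- b
      tmp <- M[i, j]; M[i, j] <- M[pick[1L], pick[2L]]
      M[pick[1L], pick[2L]] <- tmp
    }
    occ
  }
  for (seed in 1:3) {
    set.seed(seed)
    n <- 5L
    aff <- data.frame(eye = sample(c(1, -1), n * n, replace = TRUE),
                      polarity = 1, rx = seq_len(n * n), ry = 1, sigma = 2)
    sp <- structure(list(occupancy = matrix(seq_len(n * n), n, n),
                         active = matrix(TRUE, n, n),
                         afferents = aff, shape = c(n, n), pitch_um = 50),
                    class = "subplate")
    f <- make_sorting_filter(60, 120, 120)
    sp1 <- sorting_step(sp, f, "eye", seed = seed)
    expect_identical(sp1$occupancy, naive_step(sp, f, seed),
                     info = paste("seed", seed))
  }
})

test_that("sorting increases same-type neighbourhoods and preserves the bijection", {
  set.seed(8)
  n <- 16L
  aff <- data.frame(eye = sample(c(1, -1), n * n, replace = TRUE),
                    polarity = sample(c(1, -1), n * n, replace = TRUE),
                    rx = runif(n * n), ry = runif(n * n), sigma = 2)
  sp <- structure(list(occupancy = matrix(seq_len(n * n), n, n),
                       active = matrix(TRUE, n, n),
                       afferents = aff, shape = c(n, n), pitch_um = 50),
                  class = "subplate")
  f <- make_sorting_filter(100, 200, 200)
  eye0 <- matrix(aff$eye[sp$occupancy], n, n)
  frac0 <- same_neighbor_fraction(eye0)
  for (s in 1:10) {
    sp <- sorting_step(sp, f, "eye", seed = s)
    expect_equal(sort(as.vector(sp$occupancy)), seq_len(n * n))  # bijection
  }
  eye10 <- matrix(aff$eye[sp$occupancy], n, n)
  expect_gt(same_neighbor_fraction(eye10), frac0)

  ## polarity sorting never crosses an eye border
  eye_before <- eye10
  for (s in 1:5) sp <- sorting_step(sp, f, "polarity", seed = 100 + s)
  eye_after <- matrix(aff$eye[sp$occupancy], n, n)
  expect_identical(eye_after, eye_before)
})

test_that("full sorting is deterministic and n_steps = 0 is the identity", {
  set.seed(3)
  n <- 10L
  aff <- data.frame(eye = sample(c(1, -1), n * n, replace = TRUE),
                    polarity = sample(c(1, -1), n * n, replace = TRUE),
                    rx = runif(n * n), ry = runif(n * n), sigma = 2)
  sp <- structure(list(occupancy = matrix(seq_len(n * n), n, n),
                       active = matrix(TRUE, n, n),
                       afferents = aff, shape = c(n, n), pitch_um = 50),
                  class = "subplate")
  f <- make_sorting_filter(100, 200, 200)
  expect_identical(sort_afferents(sp, f, f, n_steps = 0L)$occupancy,
                   sp$occupancy)
  a <- sort_afferents(sp, f, f, n_steps = 3L, seed = 5L)
  b <- sort_afferents(sp, f, f, n_steps = 3L, seed = 5L)
  expect_identical(a$occupancy, b$occupancy)
})

test_that("elongated surrounds elongate eye domains orthogonally to the surround axis", {
  set.seed(12)
  n <- 48L
  aff <- data.frame(eye = sample(c(1, -1), n * n, replace = TRUE),
                    polarity = 1, rx = runif(n * n), ry = runif(n * n),
                    sigma = 2)
  mkplate <- function() {
    structure(list(occupancy = matrix(seq_len(n * n), n, n),
                   active = matrix(TRUE, n, n),
                   afferents = aff, shape = c(n, n), pitch_um = 50),
              class = "subplate")
  }
  run_len <- function(v) mean(rle(v)$lengths)
  anis <- function(sigma_sx, sigma_sy) {
    sp <- mkplate()
    f <- make_sorting_filter(250, sigma_sx, sigma_sy)
    for (s in 1:15) sp <- sorting_step(sp, f, "eye", seed = s)
    eye <- matrix(aff$eye[sp$occupancy], n, n)
    mean(apply(eye, 2L, run_len)) / mean(apply(eye, 1L, run_len))  # x / y
  }
  ## surround long axis along y -> domains extended along x, and vice versa
  expect_gt(anis(250, 500), anis(500, 250))
})
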