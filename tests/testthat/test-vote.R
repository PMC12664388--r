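# Independent brute-force evaluation of the four retention rules, written
# directly from their definitions and kept separate from the implementation.
oracle_retain <- function(probs, cfg = vote_config()) {
  cats <- c("brain", "muscle", "eye", "heart", "line_noise",
            "channel_noise", "other")
  v <- nrow(probs)
  bp <- probs[, "brain"]
  w <- rep(1 / v, v)
  c1 <- length(which(bp >= cfg$p_two)) >= 2
  contradiction <- FALSE
  for (i in seq_len(v)) {
    top <- cats[which.max(probs[i, ])]
    if (top != "brain" && max(probs[i, ]) >= cfg$contradiction_p)
      contradiction <- TRUE
  }
  c2 <- any(bp >= cfg$p_high) && !contradiction
  c3 <- sum(w * bp) > cfg$conservative_avg
  c4 <- length(which(sapply(seq_len(v), function(i)
    cats[which.max(probs[i, ])] == "brain" && bp[i] >= cfg$p_moderate))) > v / 2
  c1 || c2 || c3 || c4
}

test_that("classification tables are validated and renormalized", {
  path <- withr::local_tempfile(fileext = ".csv")
  ok <- data.frame(ic = 1:2, brain = c(0.8, 0.1), muscle = c(0.1, 0.6),
                   eye = 0, heart = 0, line_noise = c(0.1, 0.3),
                   channel_noise = 0, other = 0)
  write.csv(ok, path, row.names = FALSE)
  tb <- read_ic_probabilities(path, version = "clean_to_clean")
  expect_s3_class(tb, "ic_prob_table")
  expect_equal(tb$brain, c(0.8, 0.1))               # passthrough, unchanged

  off <- ok
  off$brain[1] <- 0.78                              # row sums to 0.98
  write.csv(off, path, row.names = FALSE)
  expect_warning(tb2 <- read_ic_probabilities(path), "renormalizing")
  expect_equal(rowSums(as.data.frame(tb2)[, 3:9]), c(1, 1))

  bad <- ok[, -2]                                   # missing a category
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_ic_probabilities(path), "brain")
})

test_that("the heuristic classifier labels canonical fixtures correctly", {
  fs <- fs_default
  t <- (0:7499) / fs
  diffuse <- rep(1, 16)
  single <- c(rep(0, 15), 1)
  p_alpha <- heuristic_classifier(sin(2 * pi * 10 * t), diffuse, fs)
  expect_equal(names(which.max(p_alpha)), "brain")
  p_line <- heuristic_classifier(sin(2 * pi * 50 * t), diffuse, fs)
  expect_equal(names(which.max(p_line)), "line_noise")
  spikes <- withr::with_seed(2, ifelse(runif(7500) < 0.01, 50, 0) +
                               rnorm(7500, sd = 0.5))
  p_sp <- heuristic_classifier(spikes, single, fs)
  expect_equal(names(which.max(p_sp)), "channel_noise")
  p_wh <- heuristic_classifier(withr::with_seed(3, rnorm(7500)), diffuse, fs)
  expect_lt(max(p_wh), 0.6)                         # diffuse row
  expect_equal(sum(p_wh), 1)
})

test_that("classify_components yields one normalized row per component", {
  fx <- four_source_fixture()
  m <- fit_extended_infomax(fx$rec, seed = 97)
  m$source_version <- "clean"
  dec <- apply_decomposition(m, fx$rec, "clean_to_clean")
  tb <- classify_components(dec)
  expect_equal(nrow(tb), 4)
  expect_equal(rowSums(as.matrix(as.data.frame(tb)[, -(1:2)])), rep(1, 4),
               tolerance = 1e-9)
  # the sinusoid source's component reads as brain
  act <- dec$activations
  sin_ic <- which.max(abs(cor(t(act), fx$S[3, ])))
  expect_equal(names(which.max(as.data.frame(tb)[sin_ic, -(1:2)])), "brain")
})

test_that("voting resolves the canonical worked configurations", {
  d1 <- vote_retain(brain_prob_tables(rbind(c(0.65, 0.62, 0.10))))
  expect_true(d1$retained)
  expect_true(d1$c1)

  # residual mass spread out: no non-Brain argmax reaches 0.6 anywhere
  d2 <- vote_retain(brain_prob_tables(rbind(c(0.75, 0.40, 0.35)), "spread"))
  expect_true(d2$retained)
  expect_true(d2$c2)

  d3 <- vote_retain(brain_prob_tables(rbind(c(0.20, 0.15, 0.10))))
  expect_false(d3$retained)
  expect_false(any(d3$c1, d3$c2, d3$c3, d3$c4))
})

test_that("voting agrees exactly with the brute-force oracle on the grid", {
  g <- seq(0, 1, by = 0.1)
  grid <- as.matrix(expand.grid(v1 = g, v2 = g, v3 = g))
  tables <- brain_prob_tables(grid)
  got <- vote_retain(tables)$retained
  want <- vapply(seq_len(nrow(grid)), function(i) {
    probs <- cbind(brain = grid[i, ], muscle = 0, eye = 0, heart = 0,
                   line_noise = 0, channel_noise = 0, other = 1 - grid[i, ])
    oracle_retain(probs)
  }, logical(1))
  expect_identical(got, want)
})

test_that("raising any Brain probability never removes a retained IC", {
  g <- seq(0, 1, by = 0.1)
  grid <- as.matrix(expand.grid(v1 = g, v2 = g, v3 = g))
  dec <- array(vote_retain(brain_prob_tables(grid))$retained,
               dim = c(11, 11, 11))
  expect_true(all(dec[-11, , ] <= dec[-1, , ]))
  expect_true(all(dec[, -11, ] <= dec[, -1, ]))
  expect_true(all(dec[, , -11] <= dec[, , -1]))
})

test_that("degenerate thresholds behave as documented", {
  tables <- brain_prob_tables(rbind(c(0, 0, 0), c(0.3, 0.2, 0.1)))
  all0 <- vote_config(p_two = 0, p_high = 0, conservative_avg = 0,
                      p_moderate = 0, contradiction_p = 2)
  expect_true(all(vote_retain(tables, all0)$retained))  # C1 trivially fires
  none <- vote_config(p_two = 1.01, p_high = 1.01, conservative_avg = 1.01,
                      p_moderate = 1.01, contradiction_p = 1.01)
  expect_false(any(vote_retain(tables, none)$retained))
})

test_that("a single table degrades the criteria gracefully", {
  tb <- brain_prob_tables(rbind(0.65, 0.45))[1]
  d <- vote_retain(tb)
  expect_false(any(d$c1))                # needs two versions
  expect_true(d$retained[1])             # C3 (0.65 > 0.5) and C4
  expect_false(d$retained[2])
  expect_error(vote_retain(list()), "At least one")
})

test_that("brain-signal reconstruction is exact and selective", {
  fx <- four_source_fixture()
  m <- fit_extended_infomax(fx$rec, seed = 97)
  m$source_version <- "clean"
  dec <- apply_decomposition(m, fx$rec, "clean_to_clean")

  all_in <- tibble::tibble(ic = 1:4, retained = TRUE)
  out <- reconstruct_brain_signal(dec, all_in)
  expect_equal(out$status, "ok")
  expect_lt(max(abs(out$recording$data - fx$rec$data)), 1e-6)

  none <- tibble::tibble(ic = 1:4, retained = FALSE)
  expect_equal(reconstruct_brain_signal(dec, none)$status, "excluded")

  # retain only the 10 Hz source's component
  act <- dec$activations
  cors <- abs(cor(t(act), t(fx$S)))
  sin_ic <- which.max(cors[, 3])
  art_ic <- which.max(cors[, 1])        # heavy-tailed "artifact" source
  sel <- tibble::tibble(ic = 1:4, retained = seq_len(4) == sin_ic)
  out2 <- reconstruct_brain_signal(dec, sel)
  proj_sin <- fx$A[, 3, drop = FALSE] %*% fx$S[3, , drop = FALSE]
  proj_art <- fx$A[, 1, drop = FALSE] %*% fx$S[1, , drop = FALSE]
  expect_gte(abs(correlation_to_raw(out2$recording$data, proj_sin)), 0.9)
  expect_lt(abs(correlation_to_raw(out2$recording$data, proj_art)), 0.3)
})
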