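zero_network <- function(context_mode = TRUE, hidden = 4) {
  m <- new_network(config = network_config(hidden_units = hidden, seed = 1),
                   context_mode = context_mode)
  m$w1[] <- 0; m$b1[] <- 0
  m$w2_ba[] <- 0; m$b2_ba <- 0
  m$w2_el[] <- 0; m$b2_el <- 0
  m
}

test_that("all-zero weights predict 0.5 at both heads", {
  m <- zero_network()
  p <- peptide_instance("KAAFAAAAAAAAK", 1, "EL")
  x <- encode_instance(p, 0)
  expect_equal(forward_pass(x, m, "EL"), 0.5)
  expect_equal(forward_pass(x, m, "BA"), 0.5)
})

test_that("output heads are isolated in both directions", {
  set.seed(20)
  m <- new_network(config = network_config(hidden_units = 5, seed = 2))
  p <- peptide_instance("KAAFAAAAAAAAK", 1, "EL", "ACD", "EFG")
  x <- encode_instance(p, 1)
  el0 <- forward_pass(x, m, "EL")
  ba0 <- forward_pass(x, m, "BA")
  m2 <- m; m2$w2_ba <- m2$w2_ba + rnorm(5); m2$b2_ba <- m2$b2_ba + 1
  expect_identical(forward_pass(x, m2, "EL"), el0)
  expect_false(isTRUE(all.equal(forward_pass(x, m2, "BA"), ba0)))
  m3 <- m; m3$w2_el <- m3$w2_el + rnorm(5)
  expect_identical(forward_pass(x, m3, "BA"), ba0)
})

test_that("forward pass is deterministic under the initialisation seed", {
  m1 <- new_network(config = network_config(hidden_units = 6, seed = 33))
  m2 <- new_network(config = network_config(hidden_units = 6, seed = 33))
  x <- encode_instance(peptide_instance("KAAFAAAAAAAAK", 1, "EL"), 2)
  expect_identical(forward_pass(x, m1, "EL"), forward_pass(x, m2, "EL"))
})

test_that("feature-length mismatch is rejected", {
  m <- new_network(context_mode = FALSE)
  x <- encode_instance(peptide_instance("KAAFAAAAAAAAK", 1, "EL"), 0,
                       context_mode = TRUE)
  expect_error(forward_pass(x, m, "EL"), "mismatch")
})

test_that("burn-in restricts P1 to hydrophobic residues", {
  p <- peptide_instance("KEFDAAAAAAK", 1, "EL")
  # offsets 0..2 have P1 in {K, E, F}; only F (offset 2) is hydrophobic
  for (s in 1:5) {
    m <- new_network(config = network_config(hidden_units = 4, seed = s))
    al <- select_core(p, m, iteration = 0)
    expect_equal(al$offset, 2L)
    expect_true(al$burn_in_active)
    expect_equal(al$core, "FDAAAAAAK")
  }
})

test_that("after burn-in the core is the plain arg-max over all offsets", {
  p <- peptide_instance("KEFDAAAAAAK", 1, "EL")
  m <- new_network(config = network_config(hidden_units = 4, seed = 9))
  al <- select_core(p, m, iteration = 5)
  expect_false(al$burn_in_active)
  expect_equal(al$offset, which.max(al$per_offset_scores) - 1L)
  expect_equal(length(al$per_offset_scores), 3L)
})

test_that("a 9mer always aligns at offset 0 and shorter peptides fail", {
  m <- new_network(config = network_config(hidden_units = 2, seed = 4))
  expect_equal(select_core(peptide_instance("KKKDEDKKE", 1, "EL"), m)$offset, 0L)
  expect_error(select_core(peptide_instance("KKKDEDKK", 1, "EL"), m),
               "shorter than")
})

test_that("burn-in with no hydrophobic P1 admits all offsets", {
  p <- peptide_instance("KEKDEDKEKDE", 1, "EL")
  m <- new_network(config = network_config(hidden_units = 4, seed = 12))
  al <- select_core(p, m, iteration = 0)
  expect_equal(al$offset, which.max(al$per_offset_scores) - 1L)
})

test_that("analytic gradients match central finite differences", {
  step <- 1e-5
  for (ctx in c(TRUE, FALSE)) for (head in c("EL", "BA")) {
    m <- new_network(config = network_config(hidden_units = 3, seed = 17),
                     context_mode = ctx)
    p <- peptide_instance("KAPFAYSWAADKC", 0.9, head,
                          context_up = if (ctx) "LPG" else "XXX",
                          context_down = if (ctx) "GSP" else "XXX")
    x <- encode_instance(p, 1, context_mode = ctx)$features
    target <- 0.9
    g <- mhc2lig:::.gradient(x, m, target, head)
    loss <- function(mm) 0.5 * (forward_pass(x, mm, head) - target)^2
    num <- function(set_fun) {
      mp <- set_fun(m, +step); mn <- set_fun(m, -step)
      (loss(mp) - loss(mn)) / (2 * step)
    }
    relerr <- function(a, b) abs(a - b) / pmax(abs(b), 1e-7)
    errs <- c()
    # a spread of w1 entries (including context rows when present)
    probe <- unique(round(seq(1, length(m$w1), length.out = 40)))
    for (i in probe) {
      nd <- num(function(mm, d) { mm$w1[i] <- mm$w1[i] + d; mm })
      errs <- c(errs, relerr(g$w1[i], nd))
    }
    for (i in seq_along(m$b1)) {
      nd <- num(function(mm, d) { mm$b1[i] <- mm$b1[i] + d; mm })
      errs <- c(errs, relerr(g$b1[i], nd))
    }
    w2name <- if (head == "BA") "w2_ba" else "w2_el"
    b2name <- if (head == "BA") "b2_ba" else "b2_el"
    for (i in seq_along(m[[w2name]])) {
      nd <- num(function(mm, d) { mm[[w2name]][i] <- mm[[w2name]][i] + d; mm })
      errs <- c(errs, relerr(g$w2[i], nd))
    }
    nd <- num(function(mm, d) { mm[[b2name]] <- mm[[b2name]] + d; mm })
    errs <- c(errs, relerr(g$b2, nd))
    expect_lt(max(errs), 1e-6)
  }
})

test_that("backward_update moves only the matching head and equals -lr*grad", {
  m <- new_network(config = network_config(hidden_units = 4, seed = 23))
  p <- peptide_instance("KAPFAYSWAADKC", 1, "EL", "LPG", "GSP")
  al <- select_core(p, m)
  m2 <- backward_update(p, m, al)
  expect_identical(m2$w2_ba, m$w2_ba)
  expect_identical(m2$b2_ba, m$b2_ba)
  x <- encode_instance(p, al$offset)$features
  g <- mhc2lig:::.gradient(x, m, p$target, "EL")
  lr <- m$config$learning_rate
  expect_equal(m2$w1, m$w1 - lr * g$w1, tolerance = 1e-12)
  expect_equal(m2$w2_el, m$w2_el - lr * g$w2, tolerance = 1e-12)
})

test_that("repeated updates drive the prediction monotonically to target", {
  m <- new_network(config = network_config(hidden_units = 4, seed = 31,
                                           learning_rate = 0.05))
  p <- peptide_instance("KAPFAYSWAADKC", 1, "EL", "LPG", "GSP")
  errs <- numeric(100)
  for (i in 1:100) {
    al <- select_core(p, m)
    errs[i] <- abs(forward_pass(encode_instance(p, al$offset), m, "EL") - 1)
    m <- backward_update(p, m, al)
  }
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[100], errs[1])
})

test_that("ensemble prediction averages members and is order-invariant", {
  d <- data.frame(peptide = c("KAPFAYSWAADKC", "AAKFAAAAAAAAA"),
                  target = c(1, 1), data_type = "EL",
                  context_up = "XXX", context_down = "XXX",
                  stringsAsFactors = FALSE)
  nets <- lapply(1:3, function(s)
    new_network(config = network_config(hidden_units = 3, seed = s)))
  single <- predict_ensemble(d, nets[1], "EL")
  al <- select_core(mhc2lig:::.as_instance(d[1, ]), nets[[1]])
  expect_equal(single$score[1], max(al$per_offset_scores))
  expect_equal(single$offset[1], al$offset)
  two <- predict_ensemble(d, nets[1:2], "EL")
  a <- predict_ensemble(d, nets[1], "EL")$score
  b <- predict_ensemble(d, nets[2], "EL")$score
  expect_equal(two$score, (a + b) / 2)
  perm <- predict_ensemble(d, nets[c(3, 1, 2)], "EL")
  full <- predict_ensemble(d, nets, "EL")
  expect_equal(perm$score, full$score)
  expect_equal(perm$core, full$core)
  expect_error(predict_ensemble(d, list(), "EL"), "empty ensemble")
})

test_that("the R forward pass matches the compiled prediction path", {
  set.seed(5)
  d <- data.frame(peptide = random_peptides(10), target = 1,
                  data_type = "EL", context_up = "ACD", context_down = "WYV",
                  stringsAsFactors = FALSE)
  m <- new_network(config = network_config(hidden_units = 7, seed = 3))
  pr <- predict_ensemble(d, list(m), "EL")
  for (i in seq_len(nrow(d))) {
    p <- mhc2lig:::.as_instance(d[i, ])
    al <- select_core(p, m)
    manual <- max(vapply(seq_along(al$per_offset_scores) - 1L, function(off)
      forward_pass(encode_instance(p, off), m, "EL"), numeric(1)))
    expect_equal(pr$score[i], manual, tolerance = 1e-12)
  }
})

test_that("model serialization round-trips bit-exactly", {
  ts <- tiny_training_data()
  net <- quick_network(ts$data[, 1:6])
  path <- tempfile(fileext = ".json")
  save_model(list(net), path)
  back <- load_model(path)$networks[[1]]
  expect_identical(back$w1, net$w1)
  expect_identical(back$b1, net$b1)
  expect_identical(back$w2_el, net$w2_el)
  expect_identical(back$w2_ba, net$w2_ba)
  expect_identical(back$b2_el, net$b2_el)
  expect_identical(back$context_mode, net$context_mode)
  p <- peptide_instance("KAPFAYSWAADKC", 1, "EL")
  x <- encode_instance(p, 0)
  expect_identical(forward_pass(x, back, "EL"), forward_pass(x, net, "EL"))
})
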