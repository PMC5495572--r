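test_that("quantile normalization forces the mean-of-order-statistics target", {
  m <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(quantile_normalize(m), m)

  m2 <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  q <- quantile_normalize(m2)
  expect_equal(unname(q[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, 2]), c(2.5, 3.5, 4.5))

  set.seed(51)
  r <- matrix(rlnorm(200), 50, 4,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  qr <- quantile_normalize(r)
  target <- unname(rowMeans(apply(r, 2, sort)))
  for (j in 1:4) expect_identical(unname(sort(qr[, j])), target)
  # rank preservation within columns
  for (j in 1:4) expect_identical(order(qr[, j]), order(r[, j]))
  # idempotence
  expect_equal(quantile_normalize(qr), qr)

  r[1, 1] <- NA
  expect_error(quantile_normalize(r), "NA")
  expect_error(quantile_normalize(m2[, 1, drop = FALSE]), "2 samples")
})

test_that("ties receive the mean of their tied target quantiles", {
  m <- matrix(c(1, 1, 4, 2, 3, 10), 3, 2)
  q <- quantile_normalize(m)
  # tied minimum of column 1 shares one value; column multisets still match
  expect_identical(q[1, 1], q[2, 1])
  expect_equal(sum(q[, 1]), sum(rowMeans(apply(m, 2, sort))))
})

test_that("noise estimation finds the dominant low mode", {
  # degenerate: point mass
  m0 <- matrix(7, 5, 4)
  expect_warning(n0 <- estimate_noise(m0), "identical")
  expect_identical(n0$value, 7)
  expect_true(n0$degenerate)

  # 90% tight low mode at m, 10% dispersed high component
  set.seed(52)
  low <- 2 * 2^rnorm(900, 0, 0.1)
  high <- 2^runif(100, 4, 9)
  est <- estimate_noise(matrix(c(low, high), ncol = 2))
  expect_lt(abs(est$value - 2), 0.25 * 2)
  expect_false(est$degenerate)
  expect_identical(est$scale, "log2(1+x)")
  expect_true(is.finite(est$bandwidth))

  # doubling every raw value about doubles the estimate
  est2 <- estimate_noise(matrix(2 * c(low, high), ncol = 2))
  expect_lt(abs(est2$value / est$value - 2), 0.35)
})

test_that("regularized fold change follows the noise-augmented ratio", {
  expect_identical(regularized_fc(5, 5, 1), 0)
  expect_identical(regularized_fc(1, 3, 1), 1)   # log2(4/2)
  expect_identical(regularized_fc(0, 0, 0.5), 0) # zero-expression genes
  expect_error(regularized_fc(1, 2, 0), "noise")
  expect_error(regularized_fc(1, 2, -1), "noise")
  expect_error(regularized_fc(-1, 2, 1), "non-negative")
  # printed orientation swaps numerator and denominator
  expect_identical(regularized_fc(1, 3, 1, orientation = "printed"), -1)
  # configurable base
  expect_equal(regularized_fc(0, 9, 1, log_base = 10), 1)
})

test_that("regularization shrinks fold changes monotonically in noise", {
  set.seed(53)
  a <- rlnorm(10000, 2, 1.5)
  b <- rlnorm(10000, 2, 1.5)
  n <- runif(10000, 0.01, 50)
  reg <- regularized_fc(b, a, n)
  raw <- log2(a / b)
  expect_true(all(abs(reg) <= abs(raw) + 1e-12))
  eq <- abs(a - b) < 1e-9
  expect_true(all(abs(reg[!eq]) < abs(raw[!eq])))
  # monotone decreasing magnitude in noise
  more <- regularized_fc(b, a, n * 2)
  expect_true(all(abs(more) <= abs(reg) + 1e-12))
})

test_that("de_table computes group means, sorts by |lgFC| and propagates noise", {
  m <- matrix(c(1, 3, 7, 9), 1, 4,
              dimnames = list("g1", c("c1", "c2", "t1", "t2")))
  groups <- c(c1 = "ctrl", c2 = "ctrl", t1 = "case", t2 = "case")
  tab <- de_table(m, groups, noise = 1)
  expect_equal(tab$lgFC, log2(3))  # means 2 and 8 -> log2(9/3)
  expect_equal(tab$mean_ctrl, 2)
  expect_equal(tab$mean_case, 8)

  set.seed(54)
  m2 <- matrix(rlnorm(40, 3, 1), 10, 4,
               dimnames = list(paste0("g", 1:10), names(groups)))
  m2[3, ] <- c(5, 5, 5, 5)  # planted null
  tab2 <- de_table(m2, groups, noise = 1)
  expect_identical(tab2$lgFC[tab2$gene_id == "g3"], 0)
  expect_identical(order(-abs(tab2$lgFC)), seq_len(nrow(tab2)))

  # label equivariance: permuting sample columns changes nothing
  perm <- m2[, c(3, 1, 4, 2)]
  expect_equal(de_table(perm, groups[c(3, 1, 4, 2)], noise = 1), tab2,
               ignore_attr = TRUE)

  expect_error(de_table(m2, c(c1 = "ctrl", c2 = "ctrl"), noise = 1), "condition")
})

test_that("planted fold-change signs survive the de_table route", {
  set.seed(55)
  n <- 100
  base <- rlnorm(n, 3, 1)
  fc <- numeric(n)
  fc[1:10] <- 2
  fc[11:20] <- -2
  mk <- function(cond) {
    mu <- base * if (cond == "case") 2^fc else 1
    matrix(mu * 2^rnorm(n * 3, 0, 0.15), n, 3)
  }
  m <- cbind(mk("ctrl"), mk("case"))
  dimnames(m) <- list(sprintf("g%03d", 1:n),
                      c(paste0("c", 1:3), paste0("t", 1:3)))
  groups <- setNames(rep(c("ctrl", "case"), each = 3), colnames(m))
  tab <- de_table(m, groups, noise = 0.5)
  est <- tab$lgFC[match(sprintf("g%03d", 1:20), tab$gene_id)]
  expect_true(all(sign(est) == sign(fc[1:20])))
})

test_that("outlier screen flags only genuinely discordant samples", {
  set.seed(56)
  base <- rlnorm(300, 3, 1)
  reps <- vapply(1:3, function(i) base * 2^rnorm(300, 0, 0.1),
                 numeric(300))
  impostor <- sample(reps[, 1])  # row-shuffled replicate
  m <- cbind(reps, impostor)
  colnames(m) <- c("r1", "r2", "r3", "bad")
  rownames(m) <- paste0("g", 1:300)
  rep_out <- detect_outliers(m)
  expect_identical(rep_out$sample_id[rep_out$excluded], "bad")

  # duplicate pairs: nothing flagged
  dup <- cbind(reps[, 1], reps[, 1], reps[, 2], reps[, 2])
  colnames(dup) <- paste0("s", 1:4)
  expect_false(any(detect_outliers(dup)$excluded))

  # all identical: nothing flagged
  same <- matrix(rep(base, 4), ncol = 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
  expect_false(any(detect_outliers(same)$excluded))

  # fewer than 3 samples: not applicable
  two <- detect_outliers(m[, 1:2])
  expect_false(any(two$excluded))
  expect_match(attr(two, "note"), "not applicable")

  # never excludes below 2 retained samples
  chaos <- matrix(rlnorm(300 * 3), 300, 3,
                  dimnames = list(NULL, paste0("s", 1:3)))
  rep3 <- detect_outliers(chaos, threshold = 0.99)
  expect_gte(sum(!rep3$excluded), 2L)
})

test_that("heat-map standardization clips to the display range in panel order", {
  tab <- data.frame(gene_id = c("tp53", "baxa", "pfkma", "gpib"),
                    lgFC = c(2.8, -0.3, -2.6, 0.7),
                    stringsAsFactors = FALSE)
  out <- standardize_for_heatmap(tab, c("gpib", "tp53", "pfkma", "baxa"))
  expect_identical(out$gene_id, c("gpib", "tp53", "pfkma", "baxa"))
  expect_identical(out$lgFC, c(0.7, 1.5, -1.5, -0.3))

  expect_warning(miss <- standardize_for_heatmap(tab, c("tp53", "nope")),
                 "nope")
  expect_identical(attr(miss, "missing"), "nope")
  expect_identical(miss$gene_id, "tp53")

  expect_error(standardize_for_heatmap(tab, character()), "empty")
})
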