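mk_table <- function(strains, conds = c("untreated", "treated"), reps = 6,
                     lvs = NULL, cf = NULL) {
  df <- expand.grid(replicate = seq_len(reps), condition = conds,
                    strain_id = strains, stringsAsFactors = FALSE)
  n <- nrow(df)
  df$lag_v_stall <- if (is.null(lvs)) seq_len(n) else lvs
  df$colony_fitness <- if (is.null(cf)) seq_len(n) + 0.5 else cf
  df[c("strain_id", "condition", "replicate", "lag_v_stall", "colony_fitness")]
}

test_that("duplicate plate positions pool into re-indexed replicates", {
  # one strain at 2 positions on each of 9 plates -> 18 replicates
  df <- expand.grid(row = 1, col = 1:2, replicate = 1:9, stringsAsFactors = FALSE)
  df$strain_id <- "A"; df$condition <- "untreated"
  df$lag_v_stall <- seq_len(18); df$colony_fitness <- seq_len(18)
  out <- merge_duplicates(df)
  expect_equal(sort(out$replicate), 1:18)
  # no duplicates -> identity up to ordering
  tab <- mk_table(c("A", "B"))
  out2 <- merge_duplicates(tab)
  expect_equal(dim(out2), dim(tab))
  expect_setequal(out2$lag_v_stall, tab$lag_v_stall)
  # identical full keys collide
  bad <- rbind(tab, tab[1, ])
  expect_error(merge_duplicates(bad), class = "key_collision")
})

test_that("replicate filter removes strains under-replicated in either condition", {
  tab <- rbind(mk_table("A", reps = 7)[1:12, ],   # 7 UT / 5 UVR
               mk_table("B", reps = 6),           # 6 / 6
               mk_table("C", reps = 11))          # 11 / 11
  tab$replicate[tab$strain_id == "A"] <- c(1:7, 1:5)
  tab$condition[tab$strain_id == "A"] <- c(rep("untreated", 7), rep("treated", 5))
  out <- filter_replicates(tab, 6)
  expect_setequal(unique(out$strain_id), c("B", "C"))
})

test_that("robust Z-scores have median 0 / MAD 1 and are affine-invariant", {
  expect_equal(robust_z(1:5), c(-2, -1, 0, 1, 2))
  set.seed(5)
  x <- rnorm(101)
  z <- robust_z(x)
  expect_equal(median(z), 0)
  expect_equal(median(abs(z - median(z))), 1)
  expect_equal(robust_z(3.2 * x + 17), z, tolerance = 1e-12)
  expect_error(robust_z(c(0, 0, 0, 1)), class = "degenerate_scale")
})

test_that("pooled t-test matches the hand formula, t.test, and is antisymmetric", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(r$t, 3), -3.674)
  expect_equal(r$df, 4)
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(sample(2:12, 1)); y <- rnorm(sample(2:12, 1), mean = runif(1, -1, 1))
    mine <- two_sample_t(x, y)
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    sw <- two_sample_t(y, x)
    expect_equal(sw$t, -mine$t); expect_equal(sw$p, mine$p)
  }
  # degenerate zero-variance cases
  expect_equal(two_sample_t(c(1, 1), c(1, 1))$p, 1)
  expect_equal(two_sample_t(c(1, 1), c(2, 2))$p, 0)
})

test_that("Storey q-values: cap at 1, BH identity, and the step-up oracle", {
  expect_equal(as.numeric(storey_qvalues(rep(1, 20))), rep(1, 20))
  p <- c(0.001, 0.01, 0.5, 0.8, 0.9)
  q <- storey_qvalues(p, pi0 = 1)
  expect_equal(as.numeric(q), c(0.005, 0.025, 5 * 0.5 / 3, 0.9, 0.9))
  expect_equal(as.numeric(q), stepup_oracle(p, 1))
  set.seed(7)
  for (i in 1:10) {
    pv <- runif(50)^sample(1:3, 1)
    expect_equal(as.numeric(storey_qvalues(pv, pi0 = 1)),
                 p.adjust(pv, "BH"), tolerance = 1e-12)
    qd <- as.numeric(storey_qvalues(pv))
    expect_true(all(diff(qd[order(pv)]) >= -1e-12))  # monotone in p-rank
    expect_true(all(qd >= 0 & qd <= 1))
    pi0 <- attr(storey_qvalues(pv), "pi0")
    expect_equal(qd, stepup_oracle(pv, pi0), tolerance = 1e-12)
  }
  expect_error(storey_qvalues(numeric(0)), class = "empty_input")
  expect_error(storey_qvalues(c(0.5, 1.2)), class = "invalid_pvalues")
})

test_that("nomination sets obey set algebra and an empty cutoff", {
  res <- data.frame(strain_id = c("A", "B", "B", "C"),
                    metric = c("colony_fitness", "colony_fitness",
                               "lag_v_stall", "lag_v_stall"),
                    q = c(0.01, 0.02, 0.01, 0.04),
                    delta_z = c(-1, 1, 1, -2))
  s <- nominate(res, 0.05)
  expect_equal(s$colony_fitness, c("A", "B"))
  expect_equal(s$lag_v_stall, c("B", "C"))
  expect_equal(s$union, c("A", "B", "C"))
  expect_equal(s$intersection, "B")
  expect_length(s$union, length(s$colony_fitness) + length(s$lag_v_stall) -
                  length(s$intersection))
  s0 <- nominate(res, 0)
  expect_length(s0$union, 0)
})

test_that("percentile tails have ceiling sizes and deterministic tie-breaks", {
  v <- setNames(seq_len(100), sprintf("S%03d", 1:100))
  ts <- tail_select(v, 5, 95)
  expect_length(ts$lower, 5); expect_length(ts$upper, 5)
  expect_equal(ts$lower, sprintf("S%03d", 1:5))
  expect_equal(ts$upper, sprintf("S%03d", 100:96))
  v2 <- setNames(rep(1, 40), sprintf("S%03d", 40:1))
  ts2 <- tail_select(v2, 5, 95)
  expect_length(ts2$lower, 2)
  expect_equal(ts2$lower, c("S001", "S002"))  # ties broken by strain id
  # published-scale count: N = 4294 at 5% -> 215 per tail
  v3 <- setNames(rnorm(4294), sprintf("S%04d", 1:4294))
  ts3 <- tail_select(v3, 5, 95)
  expect_length(ts3$lower, 215); expect_length(ts3$upper, 215)
})

test_that("replicate correlation: exact cases and a Monte-Carlo null", {
  x <- c(1, 2, 3, 5)
  expect_equal(replicate_correlation(x, x), 1)
  expect_equal(replicate_correlation(x, -x), -1)
  set.seed(11)
  expect_lt(abs(replicate_correlation(rnorm(1000), rnorm(1000))), 0.1)
  expect_error(replicate_correlation(c(1, 1, 1), x[1:3]),
               class = "undefined_correlation")
})

test_that("differential_screen nominates a strong responder and not a null strain", {
  set.seed(12)
  strains <- sprintf("S%03d", 1:40)
  tab <- do.call(rbind, lapply(strains, function(s) {
    d <- mk_table(s, reps = 8,
                  lvs = rnorm(16), cf = rnorm(16))
    if (s == "S001") d$colony_fitness[d$condition == "treated"] <-
        d$colony_fitness[d$condition == "treated"] - 8
    d
  }))
  scr <- differential_screen(tab, q_cutoff = 0.05)
  expect_s3_class(scr, "diff_screen")
  expect_true("S001" %in% scr$sets$colony_fitness)
  expect_false("S002" %in% scr$sets$union)
  r1 <- scr$results[scr$results$strain_id == "S001" &
                      scr$results$metric == "colony_fitness", ]
  expect_lt(r1$delta_z, 0)
  expect_equal(r1$direction, "sensitive")
  expect_output(print(scr), "Differential colony screen")
})
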