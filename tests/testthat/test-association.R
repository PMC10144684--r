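test_that("delta features compute absolute and percent changes with exclusions", {
  t0 <- c(P01 = 40, P02 = 100, P03 = 0)
  t1 <- c(P02 = 150, P01 = 20, P03 = 5)
  abs_d <- delta_feature(t0, t1, "absolute")
  expect_equal(abs_d$delta[c("P01", "P02", "P03")],
               c(P01 = -20, P02 = 50, P03 = 5))
  expect_equal(nrow(abs_d$excluded), 0L)

  pct <- delta_feature(t0, t1, "percent")
  expect_equal(pct$delta[["P01"]], -50)
  expect_equal(pct$delta[["P02"]], 50)
  expect_false("P03" %in% names(pct$delta))
  expect_equal(pct$excluded$subject_id, "P03")

  same <- delta_feature(t0[1:2], t0[1:2], "absolute")
  expect_true(all(same$delta == 0))
  expect_error(delta_feature(c(A = 1), c(B = 2)), "shared")
})

test_that("perfect monotone genes reach rho of +/- 1", {
  f <- c(s1 = 0.3, s2 = 1.1, s3 = 2.0, s4 = 5.4, s5 = 9.9)
  m <- expression_matrix(rbind(
    up = exp(seq(1, 5)), down = rev(seq(2, 10, 2)), flat = rep(3, 5)),
    sample_ids = names(f))
  res <- spearman_associate(m, f, n_top = 10)
  tab <- res$table
  expect_equal(tab$rho[tab$gene == "up"], 1)
  expect_equal(tab$rho[tab$gene == "down"], -1)
  expect_true(is.nan(tab$rho[tab$gene == "flat"]))
  expect_equal(res$top_list, "up")
  expect_equal(res$bottom_list, "down")
})

test_that("worked five-sample example matches the exhaustive rank oracle", {
  f <- stats::setNames(c(1, 2, 3, 4, 5), paste0("s", 1:5))
  g <- c(2, 1, 4, 3, 5)
  m <- expression_matrix(matrix(g, 1, dimnames = list("g1", names(f))))
  res <- spearman_associate(m, f)
  # oracle: explicit ranking then Pearson on the ranks
  expect_equal(res$table$rho, stats::cor(rank(g), rank(f)))
  expect_equal(res$table$rho, 0.8)
  # exact permutation p agrees with the reference implementation
  ct <- stats::cor.test(g, f, method = "spearman")
  expect_equal(res$table$p_value, ct$p.value, tolerance = 1e-12)
})

test_that("implementation equals the rank-then-Pearson oracle on random matrices", {
  set.seed(101)
  for (rep in 1:4) {
    m <- tiny_expr(n_genes = 50L, n_samples = 8L, seed = 200 + rep)
    f <- stats::setNames(rnorm(8), colnames(m))
    res <- spearman_associate(m, f, n_top = 50)
    oracle <- apply(unclass(m), 1, function(g) stats::cor(rank(g), rank(f)))
    expect_lt(max(abs(res$table$rho - oracle)), 1e-12)
  }
})

test_that("exact small-n p-values agree with the reference distribution", {
  set.seed(77)
  for (n in c(5L, 7L, 9L)) {
    m <- tiny_expr(n_genes = 12L, n_samples = n, seed = 300 + n)
    f <- stats::setNames(rnorm(n), colnames(m))
    res <- spearman_associate(m, f, n_top = 12)
    for (i in seq_len(nrow(res$table))) {
      ct <- stats::cor.test(unclass(m)[i, ], f, method = "spearman")
      expect_equal(res$table$p_value[i], ct$p.value, tolerance = 1e-9)
    }
  }
})

test_that("negating the feature swaps the lists and negates every rho", {
  m <- tiny_expr(n_genes = 120L, n_samples = 12L, seed = 15)
  f <- stats::setNames(rnorm(12), colnames(m))
  a <- spearman_associate(m, f, n_top = 30)
  b <- spearman_associate(m, stats::setNames(-f, names(f)), n_top = 30)
  expect_equal(b$table$rho, -a$table$rho, tolerance = 1e-12)
  expect_equal(b$top_list, a$bottom_list)
  expect_equal(b$bottom_list, a$top_list)
})

test_that("top and bottom lists are disjoint, sign-pure, and length-bounded", {
  m <- tiny_expr(n_genes = 300L, n_samples = 10L, seed = 23)
  f <- stats::setNames(rnorm(10), colnames(m))
  res <- spearman_associate(m, f, n_top = 40)
  expect_length(intersect(res$top_list, res$bottom_list), 0)
  expect_lte(length(res$top_list), 40)
  expect_lte(length(res$bottom_list), 40)
  tab <- res$table
  expect_true(all(tab$rho[match(res$top_list, tab$gene)] > 0))
  expect_true(all(tab$rho[match(res$bottom_list, tab$gene)] < 0))
  expect_true(all(abs(tab$rho) <= 1, na.rm = TRUE))
  # lists truncate at the sign boundary even when short of n_top
  expect_lt(length(res$top_list) + length(res$bottom_list), 300)
})

test_that("association rejects constant features and tiny overlaps", {
  m <- tiny_expr(n_genes = 10L, n_samples = 5L, seed = 31)
  expect_error(spearman_associate(m, stats::setNames(rep(1, 5),
                                                     colnames(m))),
               "constant")
  expect_error(spearman_associate(m, c(S01 = 1, S02 = 2)), ">= 3 samples")
})

test_that("type-I error is calibrated under the global null", {
  set.seed(55)
  n <- 20L
  m <- tiny_expr(n_genes = 1000L, n_samples = n, seed = 56)
  f <- stats::setNames(rnorm(n), colnames(m))
  res <- spearman_associate(m, f, n_top = 500)
  frac <- mean(res$table$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(frac - 0.05), 3 * se)
})

test_that("cohort overlap partitions the selected lists", {
  m <- tiny_expr(n_genes = 100L, n_samples = 10L, seed = 61)
  f <- stats::setNames(rnorm(10), colnames(m))
  res <- spearman_associate(m, f, n_top = 20)
  same <- cohort_overlap(res, res, "top")
  expect_equal(same$counts$shared, length(res$top_list))
  expect_equal(same$counts$patient_only, 0)
  expect_equal(same$counts$pdx_only, 0)

  # hand-built lists {A,B,C} vs {B,C,D}
  fake <- function(top) {
    structure(list(table = tibble::tibble(gene = c("A", "B", "C", "D"),
                                          rho = 0.5, p_value = 0.1,
                                          q_value = 0.2, n = 10),
                   top_list = top, bottom_list = character(),
                   n_samples = 10, feature_name = "f", cohort = "patient",
                   timepoint_mode = "T0"),
              class = "association_result")
  }
  ov <- cohort_overlap(fake(c("A", "B", "C")), fake(c("B", "C", "D")), "top")
  expect_equal(ov$counts, list(patient_only = 1L, pdx_only = 1L,
                               shared = 2L))
  disj <- cohort_overlap(fake(c("A", "B")), fake(c("C", "D")), "top")
  expect_equal(disj$counts$shared, 0L)
})

test_that("mismatched gene universes are restricted with a warning", {
  ma <- tiny_expr(n_genes = 60L, n_samples = 10L, seed = 71)
  mb <- expression_matrix(unclass(ma)[1:50, ], cohort = "PDX")
  f <- stats::setNames(rnorm(10), colnames(ma))
  ra <- spearman_associate(ma, f, n_top = 15)
  rb <- spearman_associate(mb, f, n_top = 15)
  expect_warning(ov <- cohort_overlap(ra, rb, "top"), "universes differ")
  expect_true(all(unlist(ov$genes) %in% rownames(mb)))
})

test_that("volcano tables carry -log10 p and conserve the tested genes", {
  m <- tiny_expr(n_genes = 80L, n_samples = 12L, seed = 81)
  raw <- unclass(m)
  raw[5, ] <- 2                      # constant gene drops out
  m <- expression_matrix(raw)
  f <- stats::setNames(rnorm(12), colnames(m))
  res <- spearman_associate(m, f, n_top = 20)
  v <- volcano_data(res)
  expect_equal(nrow(v), 79L)
  expect_false("G0005" %in% v$gene)
  expect_true(!is.unsorted(v$rho))
  i <- which.max(v$neg_log10_p)
  expect_equal(v$neg_log10_p[i],
               -log10(res$table$p_value[res$table$gene == v$gene[i]]))
  p <- plot_volcano(res)
  expect_s3_class(p, "ggplot")
})
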