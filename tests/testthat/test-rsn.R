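test_that("edges are classified within iff both endpoints share a label", {
  p <- node_partition(c("A", "A", "B"))
  cls <- classify_edges(edge_index(3), p)
  expect_equal(as.character(cls), c("within", "between", "between"))
  # one label only: everything within
  cls1 <- classify_edges(edge_index(4), node_partition(rep("A", 4)))
  expect_true(all(cls1 == "within"))
  # classes always partition the full edge set
  set.seed(16)
  p2 <- node_partition(sample(c("A", "B", "C"), 9, replace = TRUE))
  cls2 <- classify_edges(edge_index(9), p2)
  expect_equal(sum(cls2 == "within") + sum(cls2 == "between"), choose(9, 2))
})

test_that("within-edge counts match exhaustive enumeration for equal blocks", {
  K <- 4; m <- 10
  p <- node_partition(rep(paste0("B", 1:K), each = m))
  cls <- classify_edges(edge_index(K * m), p)
  # independent enumeration over all pairs
  lab <- rep(1:K, each = m); count <- 0
  for (i in 1:(K * m - 1)) for (j in (i + 1):(K * m))
    if (lab[i] == lab[j]) count <- count + 1
  expect_equal(sum(cls == "within"), count)
  expect_equal(count, K * m * (m - 1) / 2)  # 180
})

test_that("classification fails on nodes without labels", {
  p <- node_partition(c("A", "B"))
  expect_error(classify_edges(edge_index(3), p), "node 3")
})

test_that("variance contrast handles null, degenerate, and swapped-class cases", {
  p <- node_partition(c("A", "A", "A", "B", "B", "B"))  # 6 within, 9 between
  mk <- function(v) structure(list(mean = rep(0, 15), variance = v,
                                   n_windows = rep(20, 15),
                                   edge_index = edge_index(6)),
                              class = "edge_summary")
  cls <- classify_edges(edge_index(6), p)
  # identical class variances for every subject: t = 0, p = 1
  flat <- lapply(1:4, function(s) mk(rep(0.05 * s, 15)))
  r0 <- variance_contrast(flat, p)
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_false(r0$degenerate)
  # constant non-zero difference: flagged degenerate, not infinite t
  shifted <- lapply(1:3, function(s) {
    v <- rep(0.05, 15); v[cls == "between"] <- 0.08; mk(v)
  })
  rd <- variance_contrast(shifted, p)
  expect_true(rd$degenerate)
  expect_true(is.na(rd$t_statistic))
  expect_error(variance_contrast(list(mk(runif(15))), p), ">= 2")
  expect_error(variance_contrast(lapply(1:3, function(s) mk(runif(15))),
                                 node_partition(rep("A", 6))),
               "non-empty")
})

test_that("label swap negates the paired t statistic exactly", {
  # equal class sizes: 4 nodes, 3 within / 3 between under labels AAAB
  p <- node_partition(c("A", "A", "A", "B"))
  cls <- classify_edges(edge_index(4), p)
  mk <- function(v) structure(list(mean = rep(0, 6), variance = v,
                                   n_windows = rep(20, 6),
                                   edge_index = edge_index(4)),
                              class = "edge_summary")
  set.seed(18)
  subj_v <- lapply(1:6, function(s) runif(6, 0.01, 0.1))
  straight <- variance_contrast(lapply(subj_v, mk), p)
  flipped <- lapply(subj_v, function(v) {
    v2 <- v
    v2[cls == "within"] <- v[cls == "between"]
    v2[cls == "between"] <- v[cls == "within"]
    mk(v2)
  })
  reversed <- variance_contrast(flipped, p)
  expect_equal(straight$t_statistic, -reversed$t_statistic, tolerance = 1e-12)
  expect_equal(straight$p_value, reversed$p_value, tolerance = 1e-12)
})

test_that("contrast is invariant to subject order and offers an unpaired option", {
  co <- tiny_cohort(n_subjects = 4)
  sums <- lapply(co$subjects, function(s)
    summarize_edges(sliding_window_correlation(s, 30)))
  a <- variance_contrast(sums, co$partition)
  b <- variance_contrast(rev(sums), co$partition)
  expect_equal(a$t_statistic, b$t_statistic)
  expect_equal(a$p_value, b$p_value)
  u <- variance_contrast(sums, co$partition, paired = FALSE)
  expect_false(u$paired)
  expect_true(is.finite(u$t_statistic))
})

test_that("variance matrix mirrors edge variances with NA diagonal", {
  p <- node_partition(c("A", "A", "B"))
  s <- structure(list(mean = rep(0, 3), variance = c(0.01, 0.02, 0.03),
                      n_windows = rep(10, 3), edge_index = edge_index(3)),
                 class = "edge_summary")
  M <- variance_matrix(s, p)
  expect_true(all(is.na(diag(M))))
  expect_equal(M["n1", "n2"], 0.01)
  expect_equal(M["n2", "n1"], 0.01)
  expect_equal(M["n1", "n3"], 0.02)
  expect_equal(M["n2", "n3"], 0.03)
})

test_that("relabelling nodes conjugates the variance matrix consistently", {
  set.seed(19)
  n <- 6
  s <- structure(list(mean = rep(0, choose(n, 2)),
                      variance = runif(choose(n, 2), 0, 0.1),
                      n_windows = rep(10, choose(n, 2)),
                      edge_index = edge_index(n)),
                 class = "edge_summary")
  p1 <- node_partition(c("A", "B", "A", "B", "A", "B"))
  p2 <- node_partition(c("X", "Y", "X", "Y", "X", "Y"))  # same structure, new names
  M1 <- variance_matrix(s, p1)
  M2 <- variance_matrix(s, p2)
  expect_equal(unname(M1), unname(M2), ignore_attr = TRUE)
  # values are preserved under the reordering: look entries up by node id
  ids <- paste0("n", 1:n)
  expect_equal(M1[ids, ids], variance_matrix(s, node_partition(rep("Z", n)))[ids, ids])
})

test_that("block-structured cohorts show low-variance diagonal blocks", {
  co <- tiny_cohort(n_subjects = 3, n_timepoints = 240)
  sums <- lapply(co$subjects, function(s)
    summarize_edges(sliding_window_correlation(s, 45)))
  M <- variance_matrix(group_average(sums), co$partition)
  net <- attr(M, "network")
  same <- outer(net, net, "==") & upper.tri(M)
  diff <- outer(net, net, "!=") & upper.tri(M)
  expect_lt(mean(M[same]), mean(M[diff]))
})
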