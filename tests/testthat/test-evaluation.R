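test_that("confusion metrics match hand computation and conventions", {
  g <- random_network(10, 0.3, seed = 2)
  expect_equal(unlist(confusion_metrics(g, g)[c("SEN", "SPE", "F1", "MCC", "FDR")]),
               c(SEN = 1, SPE = 1, F1 = 1, MCC = 1, FDR = 0))

  # truth with 15 edges, estimate recovering 14 plus 2 false positives
  set.seed(5)
  p <- 12
  truth <- matrix(0L, p, p)
  pairs <- which(upper.tri(truth))
  tr <- sample(pairs, 15)
  truth[tr] <- 1L; truth <- truth + t(truth)
  est <- matrix(0L, p, p)
  est[tr[1:14]] <- 1L
  fp <- sample(setdiff(pairs, tr), 2)
  est[fp] <- 1L; est <- est + t(est)
  m <- confusion_metrics(est, truth)
  expect_equal(m$TP, 14); expect_equal(m$FP, 2)
  expect_equal(m$SEN, 14 / 15, tolerance = 1e-12)
  expect_equal(m$FDR, 2 / 16, tolerance = 1e-12)
  expect_equal(m$F1, 28 / 31, tolerance = 1e-12)

  # degenerate: empty estimate
  m0 <- confusion_metrics(matrix(0L, p, p), truth)
  expect_equal(c(m0$TP, m0$FDR, m0$F1, m0$MCC), c(0, 0, 0, 0))

  expect_error(confusion_metrics(est, truth[1:5, 1:5]), "dimension")
})

test_that("confusion metrics and brier agree with loop oracles on random instances", {
  for (s in 1:100) {
    set.seed(s)
    p <- sample(4:12, 1)
    truth <- random_network(p, runif(1, 0.1, 0.5))
    est <- random_network(p, runif(1, 0.1, 0.5))
    m <- confusion_metrics(est, truth)
    o <- loop_confusion(est, truth)
    expect_equal(m[names(o)], o, tolerance = 1e-12)
    expect_equal(m$TP + m$FP + m$FN + m$TN, choose(p, 2))

    prob <- matrix(0, p, p)
    prob[upper.tri(prob)] <- runif(choose(p, 2))
    prob <- prob + t(prob)
    ids <- colnames(truth)
    idx <- which(upper.tri(prob), arr.ind = TRUE)
    edges <- data.frame(gene_i = ids[idx[, 1]], gene_j = ids[idx[, 2]],
                        existence_probability = prob[idx])
    expect_equal(brier_score(edges, truth), loop_brier(prob, truth),
                 tolerance = 1e-12)
  }
})

test_that("brier score handles perfect, uniform, and relabeled predictions", {
  truth <- random_network(8, 0.3, seed = 9)
  ids <- colnames(truth)
  idx <- which(upper.tri(truth), arr.ind = TRUE)
  perfect <- data.frame(gene_i = ids[idx[, 1]], gene_j = ids[idx[, 2]],
                        existence_probability = truth[idx])
  expect_equal(brier_score(perfect, truth), 0)
  half <- perfect; half$existence_probability <- 0.5
  expect_equal(brier_score(half, truth), 0.25)
  # non-candidate pairs count as probability zero
  some <- perfect[truth[idx] == 1, ]
  expect_equal(brier_score(some, truth), 0)
  # invariant to node relabeling
  perm <- sample(8)
  truth_p <- truth[perm, perm]
  expect_equal(brier_score(perfect, truth_p), brier_score(perfect, truth))
})

test_that("hub degree counting matches the fixture", {
  fx <- m3_fixture()
  expect_equal(hub_edge_count(fx$graph, 2), 14)
  expect_equal(hub_edge_count(fx$graph, 4), 7)
  expect_equal(hub_edge_count(matrix(0L, 5, 5), 3), 0)
  expect_error(hub_edge_count(fx$graph, 99), "invalid")
})

test_that("replication studies are reproducible and summarized with SEs", {
  rs1 <- run_replication_study("M1.1", "BMRF.O", R = 2, base_seed = 7,
                               n_iter = 700, burn_in = 200)
  rs2 <- run_replication_study("M1.1", "BMRF.O", R = 2, base_seed = 7,
                               n_iter = 700, burn_in = 200)
  expect_identical(rs1$per_rep, rs2$per_rep)
  expect_true(all(rs1$summary$se >= 0))
  expect_setequal(rs1$summary$metric,
                  c("TP", "FP", "FN", "TN", "SEN", "SPE", "FDR", "MCC", "F1",
                    "brier"))
  # SE definition: sd across replications / sqrt(R)
  f1 <- rs1$per_rep$F1
  expect_equal(rs1$summary$se[rs1$summary$metric == "F1"],
               sd(f1) / sqrt(2), tolerance = 1e-12)
  expect_output(print(rs1), "BMRF.O under M1.1")

  rs3 <- run_replication_study("M3", "BMRF.O", R = 2, base_seed = 3,
                               n_iter = 700, burn_in = 200)
  expect_true(all(c("hub2", "hub4") %in% rs3$summary$metric))
})
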