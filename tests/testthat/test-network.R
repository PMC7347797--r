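test_that("correlation graph keeps edges at or above the threshold only", {
  tp <- 1:6
  m <- rbind(a = tp, b = 2 * tp + 3,          # identical shape, r = 1
             c = -tp,                         # perfectly anticorrelated
             d = rep(5, 6))                   # constant: undefined r
  g <- build_correlation_graph(m, r_min = 0.85, axis = "genes")
  expect_setequal(g$excluded, "d")
  expect_equal(nrow(g$edges), 1)
  expect_setequal(c(g$edges$from, g$edges$to), c("a", "b"))
  expect_equal(g$edges$weight, 1)
  expect_error(build_correlation_graph(m[, 1:2], 0.85), ">= 3")
})

test_that("MCL separates disconnected cliques and keeps complete graphs whole", {
  clique <- function(n) { A <- matrix(1, n, n); diag(A) <- 0; A }
  two3 <- rbind(cbind(clique(3), matrix(0, 3, 3)),
                cbind(matrix(0, 3, 3), clique(3)))
  res <- mcl_cluster(two3)
  expect_length(res$sizes, 2)
  expect_equal(unname(res$membership[1:3]),
               rep(res$membership[[1]], 3))
  res5 <- mcl_cluster(clique(5))
  expect_length(res5$sizes, 1)
  # two 4-cliques joined by a single edge split at inflation 1.7
  A <- rbind(cbind(clique(4), matrix(0, 4, 4)),
             cbind(matrix(0, 4, 4), clique(4)))
  A[4, 5] <- A[5, 4] <- 1
  res44 <- mcl_cluster(A, inflation = 1.7)
  expect_length(res44$sizes, 2)
  expect_true(same_partition(res44$membership, rep(1:2, each = 4)))
  expect_true(same_partition(res44$membership, oracle_mcl(A, 1.7)))
})

test_that("MCL agrees with the independent oracle on all tiny graphs", {
  # exhaustive over every simple graph on 4 nodes, plus the 3-node set
  for (n in 3:4) {
    pairs <- t(combn(n, 2))
    for (mask in 0:(2^nrow(pairs) - 1)) {
      A <- matrix(0, n, n)
      on <- which(bitwAnd(mask, 2^(seq_len(nrow(pairs)) - 1)) > 0)
      for (e in on) {
        A[pairs[e, 1], pairs[e, 2]] <- 1
        A[pairs[e, 2], pairs[e, 1]] <- 1
      }
      res <- mcl_cluster(A, inflation = 1.7)
      expect_true(same_partition(res$membership, oracle_mcl(A, 1.7)),
                  info = sprintf("n=%d mask=%d", n, mask))
    }
  }
})

test_that("MCL membership is a partition invariant to node order", {
  set.seed(11)
  n <- 25
  A <- matrix(0, n, n)
  idx <- which(upper.tri(A))
  on <- sample(idx, 60)
  A[on] <- runif(60, 0.5, 1)
  A <- A + t(A)
  dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  res <- mcl_cluster(A)
  expect_setequal(names(res$membership), rownames(A))
  perm <- sample(n)
  res_p <- mcl_cluster(A[perm, perm])
  expect_true(same_partition(res$membership,
                             res_p$membership[names(res$membership)]))
})

test_that("clusters never span connected components", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 18
    A <- matrix(0, n, n)
    on <- sample(which(upper.tri(A)), 25)
    A[on] <- 1; A <- A + t(A)
    comp <- local({  # label components by BFS
      lab <- rep(NA_integer_, n); cur <- 0
      for (s in 1:n) if (is.na(lab[s])) {
        cur <- cur + 1; q <- s
        while (length(q)) {
          v <- q[1]; q <- q[-1]
          if (!is.na(lab[v])) next
          lab[v] <- cur
          q <- c(q, which(A[v, ] > 0 & is.na(lab)))
        }
      }
      lab
    })
    memb <- mcl_cluster(A)$membership
    expect_true(all(tapply(comp, memb, function(x) length(unique(x))) == 1))
  }
})

test_that("cluster mean profiles average members as documented", {
  m <- rbind(x = c(1, 2, 3), y = c(9, 8, 7), z = c(5, 5, 5))
  res <- structure(list(membership = c(x = "Cluster001", y = "Cluster001",
                                       z = "Cluster002")),
                   class = "mcl_result")
  prof <- cluster_mean_profiles(res, m)
  expect_equal(unname(prof["Cluster001", ]), c(5, 5, 5))  # p and -p + c
  expect_equal(unname(prof["Cluster002", ]), c(5, 5, 5))  # singleton
  prof_max <- cluster_mean_profiles(res, m, scale = "max")
  expect_equal(unname(prof_max["Cluster002", ]), c(1, 1, 1))
})

test_that("subclustering excludes unconnectable nodes and splits mixtures", {
  set.seed(13)
  tp <- c(0, 1, 2, 4, 8, 12, 24, 48)
  up <- t(replicate(12, tp / 48 + rnorm(8, 0, 0.03)))
  down <- t(replicate(12, 1 - tp / 48 + rnorm(8, 0, 0.03)))
  m <- rbind(up, down)
  rownames(m) <- sprintf("g%02d", 1:24)
  sc <- subcluster(m, r_min = 0.95, inflation = 1.7)
  expect_true(same_partition(sc$result$membership[rownames(m)],
                             rep(1:2, each = 12)))
  # an impossible threshold excludes everything
  noisy <- matrix(rnorm(60), 10, 6,
                  dimnames = list(sprintf("n%d", 1:10), NULL))
  sc2 <- subcluster(noisy, r_min = 1)
  expect_null(sc2$result)
  expect_setequal(sc2$excluded, rownames(noisy))
  # identical profiles collapse to one subcluster
  same <- matrix(rep(tp, each = 5), 5, byrow = FALSE,
                 dimnames = list(sprintf("s%d", 1:5), NULL))
  sc3 <- subcluster(same, r_min = 0.95)
  expect_length(sc3$result$sizes, 1)
})

test_that("rand_index matches agreement counting on a known case", {
  a <- c(1, 1, 2, 2)
  b <- c(1, 1, 1, 2)
  # pairs: (12)+ (34)- (13)- (14)+ (23)- (24)+ -> 3 agreements of 6
  expect_equal(rand_index(a, b), 0.5)
  expect_equal(rand_index(letters[a], LETTERS[a]), 1)
})
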