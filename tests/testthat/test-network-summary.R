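make_parc <- function(n, networks) {
  data.frame(node_id = seq_len(n) - 1L,
             label = sprintf("n%02d", seq_len(n)),
             network = networks, hemisphere = "L",
             stringsAsFactors = FALSE)
}

test_that("nodal strengths match the hand-worked signed sums", {
  # 4 nodes, masked t: (0,1)=+2, (0,2)=-3, (2,3)=+1
  tv <- numeric(6)
  idx <- edge_index(4)
  tv[idx$i == 0 & idx$j == 1] <- 2
  tv[idx$i == 0 & idx$j == 2] <- -3
  tv[idx$i == 2 & idx$j == 3] <- 1
  map <- manual_map(4, tv, mask = tv != 0)
  parc <- make_parc(4, c("A", "A", "B", "B"))
  st <- nodal_strengths(map, parc)
  expect_equal(st$positive_strength, c(2, 2, 1, 1))
  expect_equal(st$negative_strength, c(3, 0, 3, 0))
  # empty mask: all zeros
  st0 <- nodal_strengths(manual_map(4, numeric(6), mask = rep(FALSE, 6)), parc)
  expect_true(all(st0$positive_strength == 0 & st0$negative_strength == 0))
  expect_error(nodal_strengths(map, make_parc(5, rep("A", 5))), "size")
})

test_that("handshake identity: nodal positive strengths sum to twice the masked positive edges", {
  set.seed(1)
  tv <- rnorm(edge_index(12) |> nrow())
  mask <- abs(tv) > 0.8
  map <- manual_map(12, tv, mask = mask)
  parc <- make_parc(12, rep(c("A", "B", "C"), each = 4))
  st <- nodal_strengths(map, parc)
  expect_equal(sum(st$positive_strength), 2 * sum(tv[mask & tv > 0]))
  expect_equal(sum(st$negative_strength), 2 * sum(-tv[mask & tv < 0]))
})

test_that("network summary gives closed-form t-intervals", {
  st <- data.frame(node_id = 0:2, network = "A",
                   positive_strength = c(1, 2, 3),
                   negative_strength = c(5, 5, 5))
  out <- network_summary(st)
  pos <- out[out$direction == "positive", ]
  half <- qt(0.975, 2) * sd(c(1, 2, 3)) / sqrt(3)
  expect_equal(pos$mean, 2)
  expect_equal(pos$ci95_lo, 2 - half)
  expect_equal(pos$ci95_hi, 2 + half)
  neg <- out[out$direction == "negative", ]
  expect_equal(neg$ci95_hi - neg$ci95_lo, 0)
  expect_error(network_summary(st[0, ]), "empty")
})

test_that("ANOVA residual dfs reproduce the design-shape constants", {
  set.seed(2)
  parc <- build_parcellation(415)
  mk <- function() data.frame(node_id = parc$node_id, network = parc$network,
                              positive_strength = abs(rnorm(415)),
                              negative_strength = abs(rnorm(415)))
  res3 <- hormone_network_anova(list(T = mk(), E = mk(), C = mk()), "positive")
  expect_equal(res3$residual_df, 3 * 415 - 27)   # 1218
  res2 <- sex_network_anova(list(male = mk(), female = mk()), "positive")
  expect_equal(res2$residual_df, 2 * 415 - 18)   # 812
})

test_that("two-way ANOVA F values match a hand-computed sums-of-squares oracle (balanced)", {
  # 2 hormones x 2 networks, 3 nodes per cell
  set.seed(3)
  y <- rnorm(12, mean = rep(c(0, 1, 1, 3), each = 3))
  net <- rep(rep(c("A", "B"), each = 3), 2)
  nodes <- data.frame(node_id = 0:5, network = net[1:6])
  t1 <- data.frame(node_id = 0:5, network = net[1:6],
                   positive_strength = y[1:6], negative_strength = 0)
  t2 <- data.frame(node_id = 0:5, network = net[1:6],
                   positive_strength = y[7:12], negative_strength = 0)
  res <- hormone_network_anova(list(h1 = t1, h2 = t2), "positive")
  # oracle: explicit balanced two-way sums of squares
  g <- mean(y)
  mh <- tapply(y, rep(c("h1", "h2"), each = 6), mean)
  mn <- tapply(y, net, mean)
  cellm <- tapply(y, paste(rep(c("h1", "h2"), each = 6), net), mean)
  ss_h <- 6 * sum((mh - g)^2)
  ss_n <- 6 * sum((mn - g)^2)
  ss_cells <- 3 * sum((cellm - g)^2)
  ss_int <- ss_cells - ss_h - ss_n
  ss_err <- sum((y - cellm[paste(rep(c("h1", "h2"), each = 6), net)])^2)
  tab <- res$anova
  expect_equal(tab$f[tab$term == "hormone"], (ss_h / 1) / (ss_err / 8),
               tolerance = 1e-8)
  expect_equal(tab$f[tab$term == "network"], (ss_n / 1) / (ss_err / 8),
               tolerance = 1e-8)
  expect_equal(tab$f[tab$term == "hormone:network"],
               (ss_int / 1) / (ss_err / 8), tolerance = 1e-8)
})

test_that("constructed contrasts land on the expected factor", {
  parc <- build_parcellation(36)
  mk <- function(v) data.frame(node_id = parc$node_id, network = parc$network,
                               positive_strength = v, negative_strength = 0)
  # equal within hormone, differing across hormones (plus tiny jitter for a
  # nonzero error stratum)
  set.seed(4)
  eps <- rnorm(36, sd = 1e-3)
  res <- hormone_network_anova(list(a = mk(1 + eps), b = mk(5 + eps),
                                    c = mk(9 + eps)), "positive")
  tab <- res$anova
  expect_gt(tab$f[tab$term == "hormone"], 1e4)
  expect_lt(tab$f[tab$term == "network"], 5)
  # identical tables for both participants: sex effect vanishes
  res2 <- sex_network_anova(list(m = mk(eps), f = mk(eps)), "positive")
  expect_lt(res2$anova$f[res2$anova$term == "sex"], 1e-10)
  # Tukey-significant pairs are a subset of unadjusted-significant pairs
  tuk <- res$tukey$hormone
  df <- res$residual_df
  se <- (tuk[, "upr"] - tuk[, "lwr"]) / 2 / (qtukey(0.95, 3, df) / sqrt(2))
  unadj <- 2 * pt(-abs(tuk[, "diff"] / se), df)
  expect_true(all(tuk[, "p adj"] >= 0.05 - 1e-12 | unadj < 0.05))
})

test_that("top_nodes sorts descending with deterministic node-id tie-breaks", {
  st <- data.frame(node_id = 0:2, network = "A",
                   positive_strength = c(5, 1, 9), negative_strength = 0)
  expect_equal(top_nodes(st, 3)$node_id, c(2, 0, 1))
  st2 <- data.frame(node_id = 0:3, network = "A",
                    positive_strength = c(2, 7, 7, 1), negative_strength = 0)
  expect_equal(top_nodes(st2, 4)$node_id, c(1, 2, 0, 3))
  st0 <- data.frame(node_id = 0:2, network = "A",
                    positive_strength = 0, negative_strength = 0)
  out <- top_nodes(st0, 3)
  expect_true(isTRUE(attr(out, "degenerate")))
  expect_equal(out$node_id, 0:2)
})
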