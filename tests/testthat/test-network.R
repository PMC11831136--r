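# brute-force delay-correlation oracle, directly from the overlap definition
delay_curve_oracle <- function(x, y, delayt, method = "pearson") {
  n <- length(x)
  ov <- delayt:n
  c1 <- sapply(ov, function(i) suppressWarnings(
    stats::cor(x[1:i], y[(n - i + 1):n], method = method)))
  c2 <- sapply(ov, function(i) suppressWarnings(
    stats::cor(y[1:i], x[(n - i + 1):n], method = method)))
  tibble::tibble(delay = -(n - delayt):(n - delayt),
                 corr = c(c1[-length(c1)], rev(c2)))
}

test_that("delay curves match the overlap definition and peak correctly", {
  set.seed(24)
  x <- sigmoid01(seq(0, 1, length.out = 100), 0.5, 0.08) +
    stats::rnorm(100, 0, 0.02)
  y <- sigmoid01(seq(0, 1, length.out = 100), 0.5, 0.08) +
    stats::rnorm(100, 0, 0.02)

  for (meth in c("pearson", "spearman")) {
    cur <- delay_correlation(x, y, delayt = 45, method = meth)
    orc <- delay_curve_oracle(x, y, 45, method = meth)
    expect_equal(cur$delay, orc$delay)
    expect_equal(cur$corr, orc$corr, tolerance = 1e-12)
  }

  # identity: maximum at delay 0 with corr 1
  cur_id <- delay_correlation(x, x, delayt = 45, method = "pearson")
  expect_equal(cur_id$delay[which.max(cur_id$corr)], 0)
  expect_equal(max(cur_id$corr, na.rm = TRUE), 1)

  # y trailing x by 3 -> peak at -3 (+-1); swapped at +3
  set.seed(25)
  base <- sigmoid01(seq(0, 1, length.out = 100), 0.5, 0.08)
  x3 <- base + stats::rnorm(100, 0, 0.02)
  y3 <- c(rep(base[1], 3), base[1:97]) + stats::rnorm(100, 0, 0.02)
  cur3 <- delay_correlation(x3, y3, delayt = 45, method = "pearson")
  best <- cur3$delay[which.max(cur3$corr)]
  expect_lte(abs(best - (-3)), 1)
  cur3s <- delay_correlation(y3, x3, delayt = 45, method = "pearson")
  expect_lte(abs(cur3s$delay[which.max(cur3s$corr)] - 3), 1)

  # delayt = n: single usable overlap per direction
  cur_b <- delay_correlation(x, y, delayt = 100)
  expect_equal(nrow(cur_b), 1)
  expect_equal(cur_b$delay, 0)

  expect_error(delay_correlation(x, y, delayt = 2), "delayt")
})

test_that("best delays recover planted chains and ignore enumeration order", {
  chain <- plant_delay_chain(sigmoid01(seq(0, 1, length.out = 120), 0.5, 0.07),
                             delays = c(0, 3, 7), noise_sd = 0.02, seed = 26)
  truth <- attr(chain, "true_delays")
  prof <- tbl_profile(chain)
  pairs <- best_delays(prof, delayt_fraction = 0.45, method = "pearson")
  got <- dplyr::left_join(truth, pairs, by = c("a", "b"),
                          suffix = c("_true", ""))
  expect_true(all(abs(got$delay - got$delay_true) <= 1))

  # row-order invariance
  pairs_rev <- best_delays(prof[rev(seq_len(nrow(prof))), ],
                           delayt_fraction = 0.45, method = "pearson")
  key <- function(p) {
    swap <- p$a > p$b
    tibble::tibble(a = ifelse(swap, p$b, p$a), b = ifelse(swap, p$a, p$b),
                   delay = ifelse(swap, -p$delay, p$delay), corr = p$corr)
  }
  a1 <- dplyr::arrange(key(pairs), a, b)
  a2 <- dplyr::arrange(key(pairs_rev), a, b)
  expect_equal(a1, a2)

  # identical pair at delay 0 with corr 1 (rank method, two identical rows)
  m <- rbind(A = sigmoid01(seq(0, 1, 1 / 99), 0.4, 0.1) + sin(1:100 / 9) * 0.05,
             B = sigmoid01(seq(0, 1, 1 / 99), 0.4, 0.1) + sin(1:100 / 9) * 0.05,
             C = c(rep(0, 5), sigmoid01(seq(0, 1, 1 / 99), 0.4, 0.1)[1:95]))
  colnames(m) <- sprintf("g%03d", 1:100)
  p2 <- best_delays(tbl_profile(m), method = "pearson")
  ab <- p2[p2$a == "A" & p2$b == "B", ]
  expect_equal(ab$delay, 0)
  expect_equal(ab$corr, 1)
})

test_that("worker count does not change best-delay results", {
  skip_on_os("windows")
  chain <- plant_delay_chain(sigmoid01(seq(0, 1, length.out = 80), 0.5, 0.1),
                             delays = c(0, 2, 5, 9), noise_sd = 0.03, seed = 27)
  prof <- tbl_profile(chain)
  p1 <- best_delays(prof, method = "pearson", workers = 1)
  p2 <- best_delays(prof, method = "pearson", workers = 2)
  expect_equal(p1, p2)
})

test_that("directed edges honor the strict delay limit and sign flip", {
  pairs <- tibble::tibble(
    a = c("A", "A", "A", "B"), b = c("B", "C", "D", "C"),
    delay = c(20L, -5L, 0L, 19L), corr = c(0.9, 0.8, 0.7, 0.6))
  net <- build_directed_edges(pairs, delay_limit = 20)
  e <- net$edges
  # delay 20 removed (strict); delay -5 -> single edge C->A with +5
  expect_false(any(e$source == "A" & e$target == "B"))
  expect_false(any(e$source == "B" & e$target == "A"))
  expect_equal(e[e$source == "C" & e$target == "A", ]$delay, 5)
  expect_false(any(e$source == "A" & e$target == "C"))
  # delay 0 appears in both directions
  expect_equal(sort(e$delay[(e$source == "A" & e$target == "D") |
                              (e$source == "D" & e$target == "A")]), c(0, 0))
  # positive delay kept as-is; its reversal (negative) is dropped
  expect_equal(e[e$source == "B" & e$target == "C", ]$delay, 19)
  expect_false(any(e$source == "C" & e$target == "B"))
  expect_true(all(e$delay >= 0))
  expect_setequal(net$nodes, c("A", "B", "C", "D"))
})

test_that("DPI pruning removes explained edges in a single pass", {
  mk_net <- function(edges) {
    structure(list(edges = edges,
                   nodes = sort(unique(c(edges$source, edges$target))),
                   dpi_tolerance = 0.1),
              class = "slicewise_network")
  }
  # hand-evaluated predicate: A->C explained through B
  net <- mk_net(tibble::tibble(
    source = c("A", "B", "A"), target = c("B", "C", "C"),
    delay = c(2, 2, 5), corr = c(0.9, 0.9, 0.8)))
  pr <- dpi_prune(net, tolerance = 0.1)
  expect_equal(paste(pr$edges$source, pr$edges$target),
               c("A B", "B C"))
  expect_equal(pr$n_pruned, 1L)
  expect_setequal(pr$nodes, c("A", "B", "C"))

  # no common intermediate -> kept
  net2 <- mk_net(tibble::tibble(source = c("A", "B"), target = c("C", "C"),
                                delay = c(5, 2), corr = c(0.8, 0.9)))
  expect_equal(nrow(dpi_prune(net2)$edges), 2)

  # a zero leg disqualifies the intermediate (strict > 0)
  net3 <- mk_net(tibble::tibble(
    source = c("A", "B", "A"), target = c("B", "C", "C"),
    delay = c(0, 5, 5), corr = c(0.9, 0.9, 0.8)))
  expect_equal(nrow(dpi_prune(net3)$edges), 3)

  # delay-sum bound: legs 3+3 = 6 > 5 * 1.1 -> kept
  net4 <- mk_net(tibble::tibble(
    source = c("A", "B", "A"), target = c("B", "C", "C"),
    delay = c(3, 3, 5), corr = c(0.9, 0.9, 0.8)))
  expect_equal(nrow(dpi_prune(net4)$edges), 3)

  # correlation bound: mean legs 0.55 < 0.8 - 0.1 -> kept
  net5 <- mk_net(tibble::tibble(
    source = c("A", "B", "A"), target = c("B", "C", "C"),
    delay = c(2, 2, 5), corr = c(0.55, 0.55, 0.8)))
  expect_equal(nrow(dpi_prune(net5)$edges), 3)

  # single pass against the original graph: pruning one edge does not
  # re-enable survivors (every edge judged on the full graph)
  net6 <- mk_net(tibble::tibble(
    source = c("A", "B", "A", "C"), target = c("B", "C", "C", "D"),
    delay = c(2, 2, 5, 1), corr = c(0.9, 0.9, 0.8, 0.9)))
  pr6 <- dpi_prune(net6)
  expect_true("C D" %in% paste(pr6$edges$source, pr6$edges$target))
  expect_false("A C" %in% paste(pr6$edges$source, pr6$edges$target))
})

test_that("planted chain: DPI keeps chain edges and drops the transitive one", {
  chain <- plant_delay_chain(sigmoid01(seq(0, 1, length.out = 120), 0.5, 0.07),
                             delays = c(0, 3, 7), noise_sd = 0.02, seed = 28)
  prof <- tbl_profile(chain)
  pairs <- best_delays(prof, delayt_fraction = 0.45, method = "pearson")
  net <- build_directed_edges(pairs, delay_limit = 20)
  pr <- dpi_prune(net, tolerance = 0.1)
  ids <- rownames(chain)  # D0_1, D3_2, D7_3; later copies trail earlier ones
  lab <- paste(pr$edges$source, pr$edges$target)
  expect_true(paste(ids[2], ids[1]) %in% lab)  # B -> A (delay 3)
  expect_true(paste(ids[3], ids[2]) %in% lab)  # C -> B (delay 4)
  expect_false(paste(ids[3], ids[1]) %in% lab) # transitive C -> A pruned
  expect_true(all(pr$edges$delay >= 0))
  # pruned set is a subset of the unpruned edges, nodes intact
  expect_true(all(paste(pr$edges$source, pr$edges$target) %in%
                    paste(net$edges$source, net$edges$target)))
  expect_identical(pr$nodes, net$nodes)
})

test_that("network export writes Cytoscape-ready CSV including delay_inv", {
  net <- structure(list(edges = tibble::tibble(
    source = c("A", "B"), target = c("B", "C"),
    delay = c(2L, 0L), corr = c(0.9, 0.8)),
    nodes = c("A", "B", "C"), dpi_tolerance = 0.1),
    class = "slicewise_network")
  path <- withr::local_tempfile(fileext = ".csv")
  export_network(net, path, slice_thickness_um = 20)
  back <- read_edge_list(path)
  expect_equal(back$delay_inv, c(1 / 3, 1))
  expect_equal(back$edge_id, c("A-B", "B-C"))
})
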