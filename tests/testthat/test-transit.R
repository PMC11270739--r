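# convenience: distance series from explicit per-frame values for a
# 2-tunnel network with constant lengths
mk_ds <- function(d_cat, d_bt, lens = c(p1a = 14, p1b = 14)) {
  n <- length(d_cat)
  L <- matrix(rep(lens, each = n), n, length(lens),
              dimnames = list(NULL, names(lens)))
  distance_series(d_cat, d_bt, L)
}

test_that("position assignment follows the three-distance rules", {
  p <- transit_params()
  ids <- c(p1a = 14, p1b = 19)
  mk1 <- function(d, b1, b2) {
    ds <- mk_ds(d, matrix(c(b1, b2), 1, 2,
                          dimnames = list(NULL, c("p1a", "p1b"))), ids)
    assign_position(ds, p)
  }
  expect_equal(mk1(20.0, 6, 12)$kind, "out_")       # 20 > 14 + 2
  expect_equal(mk1(11.9, 2.5, 12)$kind, "in_")      # 11.9 < 14 - 2
  r <- mk1(14.5, 3, 12)
  expect_equal(r$kind, "bt_"); expect_equal(r$tunnel, "p1a")
  expect_equal(mk1(14.5, 6, 12)$kind, "bt_unknown")
  expect_equal(mk1(16.0, 3, 12)$kind, "bt_")        # boundary -> band
  expect_equal(mk1(12.0, 3, 12)$kind, "bt_")        # lower boundary -> band
})

test_that("closest-bottleneck ties break by canonical tunnel order", {
  ds <- mk_ds(14.5, matrix(c(3, 3), 1, 2,
                           dimnames = list(NULL, c("p1a", "p1b"))))
  expect_equal(assign_position(ds)$tunnel, "p1a")
})

test_that("via-bottleneck crossings are detected and categorised", {
  # out_ -> bt_(p2) -> in_ : one out_in via p2
  lens <- c(p1a = 14, p2 = 12)
  bt <- rbind(c(8, 6), c(9, 0.5), c(9, 7))
  colnames(bt) <- names(lens)
  ds <- mk_ds(c(20, 12, 5), bt, lens)
  ev <- detect_transitions(ds)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, "out_in")
  expect_equal(ev$mediation, "via_bottleneck")
  expect_equal(ev$category, "p2")
  expect_equal(ev$start_frame, 1L)
  expect_equal(ev$end_frame, 3L)

  # out_ -> bt_ -> out_ : return to origin, no event
  ds2 <- mk_ds(c(20, 12, 20), bt, lens)
  expect_equal(nrow(detect_transitions(ds2)), 0L)

  # in_ -> bt_p3 -> bt_p2 -> out_ : category from the LAST band frame
  lens3 <- c(p2 = 12, p3 = 16)
  bt3 <- rbind(c(9, 11), c(9, 0.5), c(0.5, 9), c(8, 9))
  colnames(bt3) <- names(lens3)
  ds3 <- mk_ds(c(5, 15, 12.5, 20), bt3, lens3)
  ev3 <- detect_transitions(ds3)
  expect_equal(nrow(ev3), 1L)
  expect_equal(ev3$direction, "in_out")
  expect_equal(ev3$category, "p2")

  # band visit ending bt_unknown -> category unknown
  bt4 <- rbind(c(9, 11), c(7, 9), c(8, 9))
  colnames(bt4) <- names(lens3)
  ds4 <- mk_ds(c(5, 13, 20), bt4, lens3)
  ev4 <- detect_transitions(ds4)
  expect_equal(ev4$mediation, "via_bottleneck")
  expect_equal(ev4$category, "unknown")
})

test_that("direct crossings use the distance tolerance to reconcile sides", {
  # out side closest p1a; in side closest p1b with gap 0.4 -> swap to p1a
  bt <- rbind(c(6, 7), c(9.4, 9.0))
  colnames(bt) <- c("p1a", "p1b")
  ds <- mk_ds(c(20, 5), bt)
  ev <- detect_transitions(ds)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$mediation, "direct")
  expect_equal(ev$direction, "out_in")
  expect_equal(ev$category, "p1a")

  # gap 3.0 on both sides -> mixed
  bt2 <- rbind(c(6, 9), c(12, 9))
  colnames(bt2) <- c("p1a", "p1b")
  expect_equal(detect_transitions(mk_ds(c(20, 5), bt2))$category, "mixed")

  # agreeing sides need no tolerance
  bt3 <- rbind(c(6, 9), c(9, 12))
  colnames(bt3) <- c("p1a", "p1b")
  expect_equal(detect_transitions(mk_ds(c(20, 5), bt3))$category, "p1a")
})

test_that("degenerate inputs yield no events", {
  ds <- mk_ds(rep(25, 10), matrix(8, 10, 2,
                                  dimnames = list(NULL, c("p1a", "p1b"))))
  expect_equal(nrow(detect_transitions(ds)), 0L)
  # leading band frames produce no event
  bt <- rbind(c(2, 9), c(2, 9), c(8, 9))
  colnames(bt) <- c("p1a", "p1b")
  expect_equal(nrow(detect_transitions(mk_ds(c(14, 14, 20), bt))), 0L)
})

test_that("state machine matches the brute-force oracle on random series", {
  set.seed(202)
  for (i in 1:200) {
    ds <- random_distance_series(60L)
    expect_identical(detect_transitions(ds), oracle_transitions(ds),
                     label = paste("series", i))
  }
})

test_that("events are invariant under frame duplication", {
  set.seed(7)
  for (i in 1:20) {
    ds <- random_distance_series(40L)
    ev <- detect_transitions(ds)
    dup <- rep(seq_len(ds$n_frames), each = 3L)
    ds2 <- distance_series(ds$d_cat[dup], ds$d_bt[dup, , drop = FALSE],
                           ds$L[dup, , drop = FALSE])
    ev2 <- detect_transitions(ds2)
    expect_equal(ev2[c("direction", "mediation", "category")],
                 ev[c("direction", "mediation", "category")],
                 ignore_attr = TRUE)
  }
})

test_that("reversing a trajectory flips event directions, same category", {
  toy <- toy3()
  plan <- event_plan(c("p2", "p1a", "p3", "p3"),
                     c("out_in", "in_out", "out_in", "in_out"))
  w <- simulate_ligand_walk(toy, plan, seed = 5)
  ds <- build_distance_series(w$trajectory, toy$network)
  rev_idx <- rev(seq_len(ds$n_frames))
  dsr <- distance_series(ds$d_cat[rev_idx], ds$d_bt[rev_idx, ],
                         ds$L[rev_idx, ])
  ev <- detect_transitions(ds)
  evr <- detect_transitions(dsr)
  expect_equal(nrow(ev), nrow(evr))
  flip <- c(in_out = "out_in", out_in = "in_out")
  expect_equal(evr$direction, unname(rev(flip[ev$direction])))
  expect_equal(evr$category, rev(ev$category))
})

test_that("utilization counts sum and average correctly", {
  ev <- data.frame(
    scheme = "bulk",
    replicate = rep(1:3, c(10, 20, 30)),
    trajectory = 1,
    category = "p2", stringsAsFactors = FALSE)
  u <- count_utilization(ev)
  row <- u$per_scheme[u$per_scheme$category == "p2", ]
  expect_equal(row$mean, 20)
  expect_equal(row$sd, 10)               # sample sd over replicate totals

  ev2 <- data.frame(scheme = "s", replicate = 1, trajectory = 1,
                    category = rep(c("p2", "p1b", "mixed"), c(6, 3, 1)))
  u2 <- count_utilization(ev2)
  fr <- u2$per_scheme$fraction
  names(fr) <- u2$per_scheme$category
  expect_equal(fr[["p2"]], 0.6)
  expect_equal(fr[["p1b"]], 0.3)
  expect_equal(fr[["mixed"]], 0.1)
  expect_equal(sum(u2$per_scheme$fraction), 1)
  # category counts always sum to the number of events
  expect_equal(sum(u2$per_replicate[, u2$categories]), nrow(ev2))

  u0 <- count_utilization(ev2[0, ])
  expect_s3_class(u0, "utilization_table")
  expect_equal(nrow(u0$per_scheme), 0L)
})
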