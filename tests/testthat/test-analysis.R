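test_that("q_fraction counts formed contacts against the native reference", {
  ref <- coords(ts_shell$expanded_reference)
  caps <- capsomer_chains(ts_shell)
  for (cid in caps) {
    sub <- tail_contact_subset(ts_topo$contacts, ts_shell$expanded_reference,
                               cid)
    expect_equal(q_fraction(ref, sub), 1)            # reference: all formed
    expect_lt(q_fraction(coords(ts_shell$compact), sub), 0.1)
  }

  ## direct count: 4 pairs at {1.2, 1.4, 1.6, 1.8} x r_native -> 0.5
  sub <- data.frame(i = 1:4, j = 5:8, r_native = 0.4)
  mk_pos <- function(f) {
    x <- matrix(0, 8, 3)
    x[5:8, 1] <- f * 0.4
    x[1:4, 2] <- seq(0, 3, by = 1)
    x[5:8, 2] <- x[1:4, 2]
    x
  }
  x <- matrix(0, 8, 3)
  x[1:4, 2] <- 10 * (1:4); x[5:8, 2] <- 10 * (1:4)
  x[5:8, 1] <- c(1.2, 1.4, 1.6, 1.8) * 0.4
  expect_equal(q_fraction(x, sub), 0.5)
  x2 <- x; x2[5:8, 1] <- 2 * 0.4
  expect_equal(q_fraction(x2, sub), 0)
})

test_that("tail subsets respect scope, annotations and error contracts", {
  caps <- capsomer_chains(ts_shell)
  ref <- ts_shell$expanded_reference
  inter <- tail_contact_subset(ts_topo$contacts, ref, caps[1],
                               analysis_params())
  all_tc <- tail_contact_subset(ts_topo$contacts, ref, caps[1],
                                analysis_params(contact_scope = "all_tail_contacts"))
  expect_true(all(inter$intermolecular))
  expect_true(nrow(all_tc) >= nrow(inter))
  key <- function(cm) paste(cm$i, cm$j)
  expect_true(all(key(inter) %in% key(all_tc)))

  expect_error(tail_contact_subset(ts_topo$contacts, ref, "nope"),
               "no such chain")
  ## a tail range outside the chain span errors
  broken <- ref
  k <- match(caps[1], broken$chains$chain_id)
  broken$chains$tail_start[k] <- 900L
  broken$chains$tail_end[k] <- 950L
  expect_error(tail_contact_subset(ts_topo$contacts, broken, caps[1]),
               "outside")
  ## an empty restriction is an explicit error
  none <- ts_topo$contacts[0, , drop = FALSE]
  expect_error(tail_contact_subset(none, ref, caps[1]), "empty")
})

test_that("first-passage detection is inclusive and hysteresis-aware", {
  expect_null(detect_translocation(mk_trace(c(0.1, 0.5, 0.75)), 0.8))
  ev <- detect_translocation(mk_trace(c(0.1, 0.5, 0.85, 0.7, 0.9),
                                      times = c(0, 1, 2, 3, 4)), 0.8)
  expect_equal(ev$first_passage_time, 2)
  ## "at least 80%": a trace exactly at the threshold triggers
  ev2 <- detect_translocation(mk_trace(c(0.5, 0.8, 0.5), times = 0:2), 0.8)
  expect_equal(ev2$first_passage_time, 1)
  ## optional de-bouncing requires a sustained crossing
  noisy <- mk_trace(c(0.1, 0.85, 0.1, 0.9, 0.9, 0.9), times = 0:5)
  expect_equal(detect_translocation(noisy, 0.8)$first_passage_time, 1)
  expect_equal(detect_translocation(noisy, 0.8,
                                    hold_frames = 3)$first_passage_time, 3)
})

test_that("first passage is invariant to frame-stride refinement on monotone traces", {
  tfine <- seq(0, 10, by = 0.1)
  qfine <- pmin(1, tfine / 8)
  coarse <- seq(1, length(tfine), by = 10)
  ev_f <- detect_translocation(mk_trace(qfine, tfine), 0.8)
  ev_c <- detect_translocation(mk_trace(qfine[coarse], tfine[coarse]), 0.8)
  ## the coarse detection can only be at or after the fine one, and both sit
  ## at the first grid point past the true crossing
  expect_gte(ev_c$first_passage_time, ev_f$first_passage_time)
  expect_lt(ev_c$first_passage_time - ev_f$first_passage_time, 1)
  expect_equal(ev_f$first_passage_time,
               tfine[which(qfine >= 0.8)[1]])
})

test_that("position-resolved counts and N_i(t) bookkeeping are exact", {
  labels <- LETTERS[1:7]
  ## hand-built five-event fixture
  ev <- data.frame(chain_id = c("a", "b", "c", "d", "e"),
                   position_label = c("E", "E", "D", "A", "E"),
                   run_id = c("r1", "r1", "r2", "r2", "r2"),
                   first_passage_time = c(5, 7, 3, 9, 1))
  out <- count_events_by_position(ev, labels, chains_per_position = 60,
                                  n_runs = 20, time_grid = c(0, 4, 10))
  expect_equal(unname(out$counts[c("E", "D", "A", "B")]), c(3L, 1L, 1L, 0L))
  expect_equal(out$denominator, 1200)
  expect_equal(out$nit[, "E"], c(0L, 1L, 3L))
  expect_true(all(apply(out$nit, 2, function(v) all(diff(v) >= 0))))

  empty <- count_events_by_position(NULL, labels, 60, 20)
  expect_true(all(empty$counts == 0))

  dup <- rbind(ev, ev[1, ])
  expect_error(count_events_by_position(dup, labels, 60, 20),
               "consistency error")
})

test_that("ensemble statistics use the sample SD convention", {
  same <- matrix(rep(c(0, 1, 2, 3), 3), 3, 4, byrow = TRUE)
  st <- ensemble_statistics(same)
  expect_true(all(st$sd == 0))
  two <- rbind(c(2, 2), c(4, 4))
  st2 <- ensemble_statistics(two)
  expect_equal(st2$mean, c(3, 3))
  expect_equal(st2$sd, c(sqrt(2), sqrt(2)))
  expect_error(ensemble_statistics(matrix(1:4, 1)), ">= 2 runs")
  ## mean of non-decreasing curves is non-decreasing
  set.seed(8)
  curves <- t(replicate(5, cumsum(runif(20))))
  expect_true(all(diff(ensemble_statistics(curves)$mean) >= 0))
})

test_that("Q histograms normalise and find constructed peaks", {
  d <- q_probability_distribution(rep(0.5, 100))
  expect_equal(sum(d$probabilities), 1, tolerance = 1e-12)
  expect_equal(sum(d$probabilities > 0), 1)

  ## uniform samples: per-bin probability within 3 binomial SE of 1/bins
  set.seed(10)
  u <- q_probability_distribution(runif(1e5))
  p0 <- 1 / 50
  se <- sqrt(p0 * (1 - p0) / 1e5)
  expect_true(all(abs(u$probabilities - p0) < 3.5 * se))

  ## trimodal mixture at {0.1, 0.5, 0.9}: exactly one intermediate peak
  set.seed(12)
  qs <- pmin(0.999, pmax(0, c(rnorm(4000, 0.1, 0.03), rnorm(2000, 0.5, 0.03),
                              rnorm(4000, 0.9, 0.03))))
  tri <- q_probability_distribution(qs, analysis_params(peak_prominence = 0.02))
  expect_equal(sum(tri$peaks$type == "intermediate"), 1)
  expect_lt(abs(tri$peaks$q[tri$peaks$type == "intermediate"] - 0.5), 0.05)

  expect_error(q_probability_distribution(list()), "no traces")
  expect_error(q_probability_distribution(numeric(0)), "no Q samples")
})

test_that("equilibration cutoff finds the expansion plateau", {
  rg <- c(seq(2, 2.8, length.out = 21), rep(2.8, 30) + rnorm(30, 0, 0.001))
  idx <- equilibration_index(rg)
  expect_true(idx >= 15 && idx <= 22)
})

test_that("rg_trace and q_trace have one value per saved frame", {
  fr <- array(rnorm(5 * 8 * 3, sd = 0.1), dim = c(5, 8, 3))
  traj <- cg_trajectory(fr, times = 0:4)
  expect_equal(nrow(rg_trace(traj)), 5)
  sub <- data.frame(i = 1:2, j = 3:4, r_native = c(0.4, 0.5))
  tr <- q_trace(traj, sub)
  expect_length(tr$q, 5)
  expect_true(all(tr$q >= 0 & tr$q <= 1))
})
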