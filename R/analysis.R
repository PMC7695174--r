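## Observables of tail translocation kinetics.
##
## Q_i is the fraction of mature-reference contacts of a chain's terminal
## tail that are formed in a frame (a contact is "formed" when its distance
## is below formed_factor times its native distance).  A chain has completed
## trans-shell translocation at the first time Q_i reaches the threshold
## (inclusive), computed over the mature-specific *intermolecular* tail
## contacts.

#' Analysis parameters
#'
#' @param formed_factor a contact is formed when its distance is below
#'   `formed_factor` times its native distance (default 1.5).
#' @param translocation_threshold Q level defining completed translocation
#'   (default 0.8, compared inclusively).
#' @param tail_range default residue interval of the terminal tail used when
#'   a chain carries no annotation (default 2-25).
#' @param contact_scope `"intermolecular_only"` (default) or
#'   `"all_tail_contacts"`.
#' @param histogram_bins bins of the Q distribution on `[0, 1]` (default 50).
#' @param peak_prominence minimum prominence (in probability) for a peak of
#'   the Q distribution.
#' @export
analysis_params <- function(formed_factor = 1.5,
                            translocation_threshold = 0.8,
                            tail_range = c(2L, 25L),
                            contact_scope = c("intermolecular_only",
                                              "all_tail_contacts"),
                            histogram_bins = 50L,
                            peak_prominence = 0.005) {
  if (formed_factor <= 1) stop("formed_factor must be > 1")
  if (translocation_threshold <= 0 || translocation_threshold > 1) {
    stop("translocation_threshold must be in (0, 1]")
  }
  contact_scope <- match.arg(contact_scope)
  structure(list(formed_factor = formed_factor,
                 translocation_threshold = translocation_threshold,
                 tail_range = as.integer(tail_range),
                 contact_scope = contact_scope,
                 histogram_bins = as.integer(histogram_bins),
                 peak_prominence = peak_prominence),
            class = "analysis_params")
}

#' Mature-specific tail contacts of one chain
#'
#' Restricts a contact map to pairs with at least one atom in the chain's
#' terminal-tail residues; under the default scope only intermolecular pairs
#' (tail against another chain) are kept.
#'
#' @param map a `contact_map` built from the mature reference.
#' @param structure the reference [mol_structure()] (for residue/chain
#'   bookkeeping and tail annotations).
#' @param chain_id chain to analyse.
#' @param params an [analysis_params()].
#' @return the restricted `contact_map`; errors if the subset is empty (the
#'   chain cannot be analysed).
#' @export
tail_contact_subset <- function(map, structure, chain_id,
                                params = analysis_params()) {
  ann <- structure$chains
  row <- which(ann$chain_id == chain_id)
  if (length(row) == 0) stop("no such chain: ", chain_id)
  tr <- if (!is.na(ann$tail_start[row])) {
    c(ann$tail_start[row], ann$tail_end[row])
  } else {
    params$tail_range
  }
  span <- range(structure$atoms$residue_index[structure$atoms$chain_id == chain_id])
  if (tr[1] > span[2] || tr[2] < span[1]) {
    stop("tail range [", tr[1], ",", tr[2],
         "] lies outside the residue span of chain ", chain_id)
  }
  tail_atoms <- atom_indices(structure, chain_id, tr)
  in_tail <- (map$i %in% tail_atoms) | (map$j %in% tail_atoms)
  sub <- map[in_tail, , drop = FALSE]
  if (params$contact_scope == "intermolecular_only") {
    sub <- sub[sub$intermolecular, , drop = FALSE]
  }
  if (nrow(sub) == 0) {
    stop("empty tail-contact subset for chain ", chain_id,
         ": the chain cannot be analysed")
  }
  attr(sub, "chain_id") <- chain_id
  attr(sub, "position_label") <- ann$position_label[row]
  sub
}

#' Fraction of native contacts formed in a frame
#'
#' @param positions `n x 3` coordinate matrix (nm) covering the atom indices
#'   of the subset.
#' @param subset a `contact_map` (typically from [tail_contact_subset()]).
#' @param formed_factor formed criterion multiplier (default 1.5).
#' @return fraction in `[0, 1]`.
#' @export
q_fraction <- function(positions, subset, formed_factor = 1.5) {
  if (nrow(subset) == 0) stop("empty contact subset")
  positions <- as.matrix(positions)
  d <- sqrt(rowSums((positions[subset$i, , drop = FALSE] -
                       positions[subset$j, , drop = FALSE])^2))
  mean(d < formed_factor * subset$r_native)
}

#' Q time series of one chain over a trajectory
#'
#' @param trajectory a [cg_trajectory()].
#' @param subset tail-contact subset of the chain.
#' @param params an [analysis_params()].
#' @return a `q_trace`: list with `chain_id`, `position_label`, `times` and
#'   `q`.
#' @export
q_trace <- function(trajectory, subset, params = analysis_params()) {
  nf <- n_frames(trajectory)
  q <- vapply(seq_len(nf), function(i) {
    q_fraction(frame_coords(trajectory, i), subset, params$formed_factor)
  }, numeric(1))
  structure(list(chain_id = attr(subset, "chain_id"),
                 position_label = attr(subset, "position_label"),
                 times = trajectory$times, q = q),
            class = "q_trace")
}

#' Radius-of-gyration time series of a trajectory
#'
#' @param trajectory a [cg_trajectory()].
#' @param indices optional atom subset.
#' @return data.frame with `time` and `rg` (nm).
#' @export
rg_trace <- function(trajectory, indices = NULL) {
  nf <- n_frames(trajectory)
  rg <- vapply(seq_len(nf), function(i) {
    fr <- frame_coords(trajectory, i)
    if (!is.null(indices)) fr <- fr[indices, , drop = FALSE]
    radius_of_gyration(fr)
  }, numeric(1))
  data.frame(time = trajectory$times, rg = rg)
}

#' First-passage detection of completed translocation
#'
#' Returns the first time the Q trace reaches the threshold (inclusive, "at
#' least"); no hysteresis by default.  With `hold_frames > 0` the trace must
#' stay at or above the threshold for that many consecutive frames.
#'
#' @param trace a `q_trace`.
#' @param threshold Q threshold (default 0.8).
#' @param run_id optional run identifier carried into the event record.
#' @param hold_frames de-bouncing window (default 0 = first crossing).
#' @return a one-row data.frame event (`chain_id`, `position_label`,
#'   `run_id`, `first_passage_time`) or `NULL` if the threshold is never
#'   reached.
#' @export
detect_translocation <- function(trace, threshold = 0.8, run_id = NA,
                                 hold_frames = 0L) {
  hit <- trace$q >= threshold
  idx <- NA_integer_
  if (hold_frames > 0) {
    r <- rle(hit)
    ends <- cumsum(r$lengths)
    ok <- which(r$values & r$lengths >= hold_frames)
    if (length(ok) > 0) idx <- ends[ok[1]] - r$lengths[ok[1]] + 1L
  } else {
    w <- which(hit)
    if (length(w) > 0) idx <- w[1]
  }
  if (is.na(idx)) return(NULL)
  data.frame(chain_id = trace$chain_id,
             position_label = if (is.null(trace$position_label)) NA_character_
                              else trace$position_label,
             run_id = run_id,
             first_passage_time = trace$times[idx],
             stringsAsFactors = FALSE)
}

#' Position-resolved event counts and N_i(t) step curves
#'
#' @param events data.frame of translocation events (rows as returned by
#'   [detect_translocation()]), possibly empty.
#' @param position_labels label set (e.g. `LETTERS[1:7]`).
#' @param chains_per_position chains carrying each label (per run).
#' @param n_runs number of runs pooled.
#' @param time_grid optional time grid for the per-position cumulative
#'   count curves `N_i(t)`.
#' @return list with `counts` (named vector), `denominator`
#'   (`chains_per_position * n_runs`), and -- when `time_grid` is given --
#'   `nit`, a `length(time_grid) x labels` matrix of cumulative counts
#'   pooled over runs.
#' @export
count_events_by_position <- function(events, position_labels,
                                     chains_per_position, n_runs,
                                     time_grid = NULL) {
  if (!is.null(events) && nrow(events) > 0) {
    keydup <- duplicated(events[c("run_id", "chain_id")])
    if (any(keydup)) {
      stop("consistency error: duplicate event for (run, chain) ",
           paste(unique(paste(events$run_id[keydup], events$chain_id[keydup])),
                 collapse = ", "))
    }
    counts <- table(factor(events$position_label, levels = position_labels))
    counts <- stats::setNames(as.integer(counts), position_labels)
  } else {
    counts <- stats::setNames(integer(length(position_labels)), position_labels)
  }
  denom <- chains_per_position * n_runs
  if (any(counts > denom)) {
    stop("consistency error: more events than (chains x runs) for position(s) ",
         paste(position_labels[counts > denom], collapse = ", "))
  }
  out <- list(counts = counts, denominator = denom)
  if (!is.null(time_grid)) {
    nit <- matrix(0L, length(time_grid), length(position_labels),
                  dimnames = list(NULL, position_labels))
    if (!is.null(events) && nrow(events) > 0) {
      for (p in position_labels) {
        tp <- sort(events$first_passage_time[events$position_label == p])
        nit[, p] <- vapply(time_grid, function(t) sum(tp <= t), integer(1))
      }
    }
    out$nit <- nit
    out$time_grid <- time_grid
  }
  out
}

#' Ensemble mean and standard deviation of N_i(t) curves
#'
#' @param curves numeric matrix, one row per run, one column per time point
#'   (a common grid across runs).
#' @return list with `mean` and `sd` (sample SD, n-1 denominator) vectors.
#' @export
ensemble_statistics <- function(curves) {
  curves <- as.matrix(curves)
  if (nrow(curves) < 2) {
    stop("ensemble SD requires >= 2 runs (got ", nrow(curves), ")")
  }
  list(mean = colMeans(curves), sd = apply(curves, 2, sd))
}

## peak prominence: height above the higher of the two bracketing saddles
## (the minimum on the walk toward the nearest higher value on each side;
## the series edge acts as a higher value)
peak_prominences <- function(y) {
  n <- length(y)
  is_peak <- which(vapply(seq_len(n), function(i) {
    l <- if (i > 1) y[i - 1] else -Inf
    r <- if (i < n) y[i + 1] else -Inf
    y[i] > l && y[i] >= r
  }, logical(1)))
  prom <- numeric(length(is_peak))
  for (q in seq_along(is_peak)) {
    i <- is_peak[q]
    lmin <- y[i]; k <- i
    while (k > 1 && y[k - 1] <= y[i]) { k <- k - 1; lmin <- min(lmin, y[k]) }
    base_l <- if (k == 1 && y[1] <= y[i]) min(lmin, y[1]) else lmin
    rmin <- y[i]; k <- i
    while (k < n && y[k + 1] <= y[i]) { k <- k + 1; rmin <- min(rmin, y[k]) }
    base_r <- if (k == n && y[n] <= y[i]) min(rmin, y[n]) else rmin
    prom[q] <- y[i] - max(base_l, base_r)
  }
  data.frame(index = is_peak, height = y[is_peak], prominence = prom)
}

#' Q probability distribution with intermediate-peak detection
#'
#' Pools Q samples (optionally after removing an equilibration prefix from
#' each trace), histograms them on `[0, 1]`, and reports local maxima above
#' a prominence threshold, classified as endpoint (bin centre `< 0.2` or
#' `> 0.8`) or intermediate.
#'
#' @param traces a list of `q_trace` objects (or a single one), or a bare
#'   numeric vector of Q samples.
#' @param params an [analysis_params()].
#' @param equilibration number of leading frames dropped from every trace
#'   (single value or vector, one per trace).
#' @return list with `bin_edges`, `probabilities` (sums to 1), `counts` and
#'   `peaks` (data.frame `q`, `probability`, `prominence`, `type`).
#' @export
q_probability_distribution <- function(traces, params = analysis_params(),
                                       equilibration = 0L) {
  if (inherits(traces, "q_trace")) traces <- list(traces)
  if (is.numeric(traces)) {
    qs <- traces
  } else {
    if (length(traces) == 0) stop("no traces supplied")
    eq <- rep_len(as.integer(equilibration), length(traces))
    qs <- unlist(lapply(seq_along(traces), function(k) {
      q <- traces[[k]]$q
      if (eq[k] > 0 && eq[k] < length(q)) q[-seq_len(eq[k])]
      else if (eq[k] >= length(q)) numeric(0)
      else q
    }))
  }
  if (length(qs) == 0) stop("no Q samples after equilibration removal")
  nb <- params$histogram_bins
  edges <- seq(0, 1, length.out = nb + 1)
  bin <- pmin(pmax(findInterval(qs, edges, rightmost.closed = TRUE), 1L), nb)
  counts <- tabulate(bin, nbins = nb)
  probs <- counts / sum(counts)
  pk <- peak_prominences(probs)
  pk <- pk[pk$prominence >= params$peak_prominence, , drop = FALSE]
  centers <- (edges[-1] + edges[-(nb + 1)]) / 2
  peaks <- data.frame(q = centers[pk$index],
                      probability = pk$height,
                      prominence = pk$prominence)
  peaks$type <- ifelse(peaks$q < 0.2 | peaks$q > 0.8, "endpoint",
                       "intermediate")
  list(bin_edges = edges, probabilities = probs, counts = counts,
       peaks = peaks)
}

#' Equilibration cutoff from an Rg expansion trace
#'
#' The expansion phase is considered finished at the first frame where Rg
#' reaches `frac` of its plateau (mean over the final fifth of the trace).
#'
#' @param rg numeric Rg series.
#' @param frac plateau fraction (default 0.95).
#' @return frame index of the cutoff.
#' @export
equilibration_index <- function(rg, frac = 0.95) {
  plateau <- mean(tail(rg, max(1, length(rg) %/% 5)))
  idx <- which(rg >= frac * plateau)
  if (length(idx) == 0) length(rg) else idx[1]
}
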