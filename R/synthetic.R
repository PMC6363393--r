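#' Specification for a synthetic sequence dataset
#'
#' Describes a population in which groups of neurons fire in fixed
#' sequential order: each sequence consists of `neurons_per_seq`
#' consecutively active neurons separated by `gap_bins` timebins, and
#' every activation is convolved with a causal exponential kernel
#' (`kernel_tau` timebins, truncated at 5 tau) to emulate calcium
#' imaging transients.  Instances of each sequence are placed at random
#' non-overlapping times so that on average `target_instances_per_seq`
#' instances occur over the `T` timebins.
#'
#' @param n_sequences number of distinct sequences.
#' @param neurons_per_seq neurons participating in each sequence.
#' @param gap_bins timebins between consecutive neurons in a sequence.
#' @param kernel_tau exponential decay constant, in timebins.
#' @param T total number of timebins.
#' @param target_instances_per_seq expected number of instances of each
#'   sequence over the whole recording (default 60).  The realized
#'   count per sequence is Poisson with this mean, truncated by the
#'   non-overlap constraint.
#' @param shared_neuron_mode `"none"` gives every sequence its own
#'   neurons; `"same_latency"` makes half of the first sequence's
#'   neurons participate in every sequence at the same ordinal position;
#'   `"different_latency"` shares the same neurons but at reversed
#'   positions.
#' @param seed integer seed; the generator is a pure function of
#'   spec + seed.
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(n_sequences = 3L, neurons_per_seq = 10L,
                          gap_bins = 3L, kernel_tau = 10,
                          T = 15000L, target_instances_per_seq = 60,
                          shared_neuron_mode = c("none", "same_latency",
                                                 "different_latency"),
                          seed = 1L) {
  shared_neuron_mode <- match.arg(shared_neuron_mode)
  stopifnot(n_sequences >= 1, neurons_per_seq >= 1, gap_bins >= 1,
            kernel_tau > 0, T >= 1)
  if (is.null(target_instances_per_seq))
    target_instances_per_seq <- 60
  duration <- (neurons_per_seq - 1L) * gap_bins + 1L
  if (duration > T)
    stop("sequence_spec: sequence duration exceeds T")
  structure(list(n_sequences = as.integer(n_sequences),
                 neurons_per_seq = as.integer(neurons_per_seq),
                 gap_bins = as.integer(gap_bins),
                 kernel_tau = kernel_tau,
                 T = as.integer(T),
                 target_instances_per_seq = target_instances_per_seq,
                 shared_neuron_mode = shared_neuron_mode,
                 seed = as.integer(seed)),
            class = "sequence_spec")
}

# causal exponential kernel, truncated at 5 tau, left aligned
exp_kernel <- function(tau) exp(-(0:ceiling(5 * tau)) / tau)

# neuron identity and ordinal position of every sequence member
seq_membership <- function(spec) {
  nps <- spec$neurons_per_seq
  ns <- spec$n_sequences
  mode <- spec$shared_neuron_mode
  members <- vector("list", ns)
  if (mode == "none" || ns == 1L) {
    for (k in seq_len(ns))
      members[[k]] <- data.frame(neuron = (k - 1L) * nps + seq_len(nps),
                                 pos = seq_len(nps))
    n_total <- nps * ns
  } else {
    n_shared <- floor(nps / 2)
    own <- nps - n_shared
    members[[1L]] <- data.frame(neuron = seq_len(nps), pos = seq_len(nps))
    for (k in 2L:ns) {
      own_ids <- nps + (k - 2L) * own + seq_len(own)
      if (mode == "same_latency") {
        shared_pos <- seq_len(n_shared)
      } else {
        shared_pos <- nps - seq_len(n_shared) + 1L   # reversed latencies
      }
      own_pos <- setdiff(seq_len(nps), shared_pos)
      members[[k]] <- data.frame(
        neuron = c(seq_len(n_shared), own_ids),
        pos = c(shared_pos, own_pos))
    }
    n_total <- nps + (ns - 1L) * own
  }
  list(members = members, n_total = n_total)
}

# place instance onsets (0-based) for one sequence: Poisson count,
# uniform candidates, rejection of overlaps with already-placed
# instances of the same sequence.  `span` is the exclusion window (the
# sequence duration; kernel tails of consecutive instances may overlap)
place_instances <- function(n_target, T, span) {
  if (n_target == 0L) return(integer(0))
  max_onset <- T - span
  if (max_onset < 0L) stop("place_instances: sequence longer than T")
  accepted <- integer(0)
  occupied <- logical(T)
  attempts <- 0L
  max_attempts <- 50L * n_target
  while (length(accepted) < n_target && attempts < max_attempts) {
    attempts <- attempts + 1L
    cand <- sample.int(max_onset + 1L, 1L) - 1L
    idx <- (cand + 1L):(cand + span)
    if (!any(occupied[idx])) {
      occupied[idx] <- TRUE
      accepted <- c(accepted, cand)
    }
  }
  sort(accepted)
}

# render an event table into the data matrix by dropping one kernel
# copy at each event time (clipped at the right edge)
build_X_from_events <- function(events, N, T, kernel) {
  X <- matrix(0, N, T)
  klen <- length(kernel)
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      t0 <- events$time[i]
      if (is.na(t0) || t0 < 0L || t0 >= T) next
      len <- min(klen, T - t0)
      cols <- (t0 + 1L):(t0 + len)
      X[events$neuron[i], cols] <- X[events$neuron[i], cols] +
        events$amplitude[i] * kernel[seq_len(len)]
    }
  }
  X
}

# ground-truth factor model implied by the membership table
truth_model <- function(spec, mem, events, kernel) {
  duration <- (spec$neurons_per_seq - 1L) * spec$gap_bins + 1L
  L <- duration + length(kernel) - 1L
  K <- spec$n_sequences
  W <- array(0, c(mem$n_total, K, L))
  for (k in seq_len(K)) {
    mk <- mem$members[[k]]
    for (j in seq_len(nrow(mk))) {
      lag0 <- (mk$pos[j] - 1L) * spec$gap_bins
      idx <- lag0 + seq_along(kernel)
      W[mk$neuron[j], k, idx] <- W[mk$neuron[j], k, idx] + kernel
    }
  }
  H <- matrix(0, K, spec$T)
  ev <- events[!is.na(events$sequence) & events$pos == 1L, ]
  for (i in seq_len(nrow(ev)))
    H[ev$sequence[i], ev$onset[i] + 1L] <-
      H[ev$sequence[i], ev$onset[i] + 1L] + 1
  factor_model(W, H)
}

#' Generate a synthetic sequence dataset
#'
#' Places instances of each sequence at random non-overlapping times
#' (instances of different sequences may overlap freely), builds the
#' binary event raster, and convolves it with the exponential kernel.
#' The returned object carries the exact event log, the ground-truth
#' factor model (whose reconstruction equals `X` exactly in the absence
#' of noise), and a log of any noise operations applied afterwards.
#'
#' @param spec a [sequence_spec()].
#' @return An object of class `synthetic_dataset` with elements `X`
#'   (a [data_matrix()]), `truth` (a [factor_model()]), `events`
#'   (data frame: `sequence`, `instance`, `onset`, `neuron`, `pos`,
#'   `time`, `amplitude`), `spec`, `kernel`, and `noise_log`.
#' @examples
#' ds <- make_sequences(sequence_spec(T = 2000,
#'                                    target_instances_per_seq = 8,
#'                                    seed = 7))
#' nrow(ds$events)
#' @export
make_sequences <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  kernel <- exp_kernel(spec$kernel_tau)
  duration <- (spec$neurons_per_seq - 1L) * spec$gap_bins + 1L
  span <- duration + length(kernel) - 1L
  if (spec$target_instances_per_seq * duration > 0.9 * spec$T)
    stop("make_sequences: requested instance rate cannot satisfy the ",
         "non-overlap constraint; lower target_instances_per_seq or raise T")
  set.seed(spec$seed)
  mem <- seq_membership(spec)
  ev_list <- list()
  for (k in seq_len(spec$n_sequences)) {
    n_inst <- rpois(1L, spec$target_instances_per_seq)
    onsets <- place_instances(n_inst, spec$T, duration)
    mk <- mem$members[[k]]
    if (length(onsets)) {
      grid <- expand.grid(i = seq_along(onsets), j = seq_len(nrow(mk)))
      ev_list[[k]] <- data.frame(
        sequence = k,
        instance = grid$i,
        onset = onsets[grid$i],
        neuron = mk$neuron[grid$j],
        pos = mk$pos[grid$j],
        time = onsets[grid$i] + (mk$pos[grid$j] - 1L) * spec$gap_bins,
        amplitude = 1)
    }
  }
  events <- do.call(rbind, ev_list)
  if (is.null(events))
    events <- data.frame(sequence = integer(0), instance = integer(0),
                         onset = integer(0), neuron = integer(0),
                         pos = integer(0), time = integer(0),
                         amplitude = numeric(0))
  X <- build_X_from_events(events, mem$n_total, spec$T, kernel)
  structure(list(X = data_matrix(X),
                 truth = truth_model(spec, mem, events, kernel),
                 events = events,
                 spec = spec,
                 membership = mem,
                 kernel = kernel,
                 duration = duration,
                 span = span,
                 noise_log = list()),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d channels x %d timebins, %d sequences, %d events\n",
    nrow(x$X$X), ncol(x$X$X),
    length(unique(stats::na.omit(x$events$sequence))), nrow(x$events)))
  if (length(x$noise_log))
    cat("  noise:", paste(vapply(x$noise_log, `[[`, "", "op"),
                          collapse = ", "), "\n")
  invisible(x)
}

# rebuild X after the event log has been modified
regen_dataset <- function(ds, events, log_entry) {
  ds$events <- events
  ds$X <- data_matrix(build_X_from_events(events, nrow(ds$X$X),
                                          ds$spec$T, ds$kernel))
  ds$noise_log <- c(ds$noise_log, list(log_entry))
  ds
}

#' Participation noise
#'
#' Each (neuron, instance) event of a sequence is independently
#' retained with probability `p`; the data matrix is regenerated from
#' the surviving events.  Models neurons that skip some renditions of
#' their sequence.
#'
#' @param ds a [make_sequences()] dataset.
#' @param p retention probability in `[0, 1]`.
#' @param seed integer seed.
#' @return The modified `synthetic_dataset`.
#' @export
apply_participation <- function(ds, p, seed = 1L) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop("apply_participation: p must lie in [0, 1]")
  set.seed(seed)
  is_seq <- !is.na(ds$events$sequence)
  keep <- !is_seq | (runif(nrow(ds$events)) < p)
  regen_dataset(ds, ds$events[keep, , drop = FALSE],
                list(op = "participation", p = p, seed = seed))
}

#' Additive noise
#'
#' Spurious events are placed independently at each (neuron, timebin)
#' cell with probability `rate`, convolved with the same kernel, and
#' added to the data.
#'
#' @param ds a [make_sequences()] dataset.
#' @param rate probability of a spurious event per cell (e.g. 0.01 for
#'   the 1 percent condition).
#' @param seed integer seed.
#' @return The modified `synthetic_dataset`.
#' @export
apply_additive <- function(ds, rate, seed = 1L) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0)
    stop("apply_additive: rate must be >= 0")
  set.seed(seed)
  N <- nrow(ds$X$X); T <- ds$spec$T
  hit <- which(runif(N * T) < rate) - 1L
  if (length(hit)) {
    extra <- data.frame(sequence = NA_integer_, instance = NA_integer_,
                        onset = NA_integer_,
                        neuron = hit %% N + 1L,
                        pos = NA_integer_,
                        time = hit %/% N,
                        amplitude = 1)
    events <- rbind(ds$events, extra)
  } else events <- ds$events
  regen_dataset(ds, events,
                list(op = "additive", rate = rate, seed = seed,
                     n_added = length(hit)))
}

#' Temporal jitter noise
#'
#' Each sequence event time is displaced by `round(rnorm(0, sigma))`
#' timebins, clipped to the recording, and the data regenerated.
#'
#' @param ds a [make_sequences()] dataset.
#' @param sigma standard deviation of the displacement, in timebins.
#' @param seed integer seed.
#' @return The modified `synthetic_dataset`.
#' @export
apply_jitter <- function(ds, sigma, seed = 1L) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("apply_jitter: sigma must be >= 0")
  if (sigma == 0) {
    ds$noise_log <- c(ds$noise_log,
                      list(list(op = "jitter", sigma = 0, seed = seed)))
    return(ds)
  }
  set.seed(seed)
  ev <- ds$events
  is_seq <- !is.na(ev$sequence)
  disp <- round(rnorm(sum(is_seq), 0, sigma))
  ev$time[is_seq] <- pmin(pmax(ev$time[is_seq] + disp, 0L),
                          ds$spec$T - 1L)
  regen_dataset(ds, ev, list(op = "jitter", sigma = sigma, seed = seed))
}

#' Temporal warping noise
#'
#' Each sequence instance is assigned a stretch factor drawn uniformly
#' from `[1, 1 + max_stretch_pct/100]`; the within-instance event
#' offsets are scaled by that factor (rounded to integer bins).
#' Instances whose stretched extent would overlap another instance of
#' the same sequence, or run off the recording, are re-placed at a
#' fresh random onset by rejection.
#'
#' @param ds a [make_sequences()] dataset.
#' @param max_stretch_pct maximum stretch, in percent (e.g. 266).
#' @param seed integer seed.
#' @return The modified `synthetic_dataset`.
#' @export
apply_warp <- function(ds, max_stretch_pct, seed = 1L) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  if (!is.numeric(max_stretch_pct) || length(max_stretch_pct) != 1L ||
      max_stretch_pct < 0)
    stop("apply_warp: max_stretch_pct must be >= 0")
  set.seed(seed)
  ev <- ds$events
  T <- ds$spec$T
  klen <- length(ds$kernel)
  for (k in unique(stats::na.omit(ev$sequence))) {
    rows_k <- which(ev$sequence %in% k)
    insts <- unique(ev$instance[rows_k])
    occupied <- logical(T)
    placed <- list()
    for (i in insts) {
      rows <- rows_k[ev$instance[rows_k] == i]
      u <- runif(1L, 1, 1 + max_stretch_pct / 100)
      onset <- ev$onset[rows][1L]
      offs <- round((ev$time[rows] - onset) * u)
      span_i <- max(offs) + 1L      # active duration; kernel tails may overlap
      if (span_i > T)
        stop("apply_warp: stretched instance longer than the recording")
      ok <- onset + span_i <= T &&
        !any(occupied[(onset + 1L):(onset + span_i)])
      if (!ok) {        # re-place by rejection
        for (try in seq_len(200L)) {
          cand <- sample.int(T - span_i + 1L, 1L) - 1L
          if (!any(occupied[(cand + 1L):(cand + span_i)])) {
            onset <- cand; ok <- TRUE; break
          }
        }
      }
      if (!ok) { ev$amplitude[rows] <- 0; next }  # drop unplaceable
      occupied[(onset + 1L):(onset + span_i)] <- TRUE
      ev$onset[rows] <- onset
      ev$time[rows] <- onset + offs
    }
  }
  ev <- ev[is.na(ev$sequence) | ev$amplitude > 0, , drop = FALSE]
  regen_dataset(ds, ev, list(op = "warp",
                             max_stretch_pct = max_stretch_pct,
                             seed = seed))
}

#' Synchronous/sequential mixture datasets
#'
#' Generates the benchmark used to calibrate the sequenciness score:
#' a population of `n_neurons` neurons emits repeated pattern
#' occurrences, each of which is, with probability `p_sequence`, an
#' asynchronous sequence (one neuron per timebin, no cross-neuron
#' synchrony) and otherwise a synchronous event (all neurons in the
#' same timebin).  Events are single-bin impulses by default
#' (`kernel_tau = 0`): any temporal kernel wider than the one-bin gap
#' would smear consecutive sequence events into partly synchronous
#' activity and dilute the contrast the score is calibrated on.
#' Additive noise is sprinkled at `noise_rate` per cell.
#'
#' @param n_neurons number of neurons (default 10).
#' @param T number of timebins (default 3000).
#' @param p_sequence probability that an occurrence is sequential.
#' @param noise_rate additive noise probability per (neuron, timebin).
#' @param mean_occurrences expected number of pattern occurrences.
#' @param kernel_tau exponential kernel decay in bins; 0 for impulses.
#' @param seed integer seed.
#' @return A `synthetic_dataset`; `events$sequence` is 1 for
#'   sequential occurrences and 2 for synchronous ones.
#' @export
make_mixture <- function(n_neurons = 10L, T = 3000L, p_sequence = 0.5,
                         noise_rate = 0.002, mean_occurrences = 40,
                         kernel_tau = 0, seed = 1L) {
  stopifnot(n_neurons >= 1, T >= 1,
            p_sequence >= 0, p_sequence <= 1, noise_rate >= 0,
            kernel_tau >= 0)
  set.seed(seed)
  kernel <- if (kernel_tau > 0) exp_kernel(kernel_tau) else 1
  span <- n_neurons + length(kernel) - 1L
  n_occ <- rpois(1L, mean_occurrences)
  onsets <- place_instances(n_occ, T, span)
  is_seq <- runif(length(onsets)) < p_sequence
  ev_list <- lapply(seq_along(onsets), function(i) {
    offs <- if (is_seq[i]) seq_len(n_neurons) - 1L else rep(0L, n_neurons)
    data.frame(sequence = if (is_seq[i]) 1L else 2L,
               instance = i, onset = onsets[i],
               neuron = seq_len(n_neurons), pos = seq_len(n_neurons),
               time = onsets[i] + offs, amplitude = 1)
  })
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(sequence = integer(0), instance = integer(0),
               onset = integer(0), neuron = integer(0), pos = integer(0),
               time = integer(0), amplitude = numeric(0))
  # ground truth: one sequential and one synchronous pattern
  L <- span
  W <- array(0, c(n_neurons, 2L, L))
  for (j in seq_len(n_neurons)) {
    W[j, 1L, (j - 1L) + seq_along(kernel)] <- kernel
    W[j, 2L, seq_along(kernel)] <- kernel
  }
  H <- matrix(0, 2L, T)
  for (i in seq_along(onsets))
    H[if (is_seq[i]) 1L else 2L, onsets[i] + 1L] <- 1
  ds <- structure(list(X = NULL, truth = factor_model(W, H),
                       events = events,
                       spec = list(T = as.integer(T),
                                   n_sequences = 2L,
                                   seed = as.integer(seed)),
                       kernel = kernel,
                       duration = n_neurons, span = span,
                       noise_log = list(list(op = "mixture",
                                             p_sequence = p_sequence,
                                             noise_rate = noise_rate,
                                             seed = seed))),
                  class = "synthetic_dataset")
  X <- build_X_from_events(events, n_neurons, T, kernel)
  if (noise_rate > 0) {
    hit <- which(runif(n_neurons * T) < noise_rate) - 1L
    for (h in hit) {
      n <- h %% n_neurons + 1L; t0 <- h %/% n_neurons
      len <- min(length(kernel), T - t0)
      X[n, (t0 + 1L):(t0 + len)] <- X[n, (t0 + 1L):(t0 + len)] +
        kernel[seq_len(len)]
    }
  }
  ds$X <- data_matrix(X)
  ds
}
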