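# Linear-chain CRF over the BIOES label set.
#
# A path score is start[y1] + sum_t emit[t, yt] + sum_{t>1} trans[y_{t-1},
# y_t] + stop[yT]; the partition function is computed by the forward
# algorithm in log space and the loss is the negative log-likelihood of
# the gold path.  Gradients come from forward-backward posteriors.
# Invalid BIOES transitions are not hard-masked: the transition matrix
# learns them, and the decoder repairs any residue.

#' Initialize CRF parameters
#'
#' @param labels Label set (default the 33 BIOES labels).
#' @param init_sd Standard deviation of the small random initialization.
#' @return List with `transitions` (L x L, from -> to), `start_scores`,
#'   `stop_scores` and `labels`.
#' @export
crf_params <- function(labels = bioes_labels(), init_sd = 0.01) {
  L <- length(labels)
  list(transitions = matrix(stats::rnorm(L * L, sd = init_sd), L, L,
                            dimnames = list(labels, labels)),
       start_scores = stats::rnorm(L, sd = init_sd),
       stop_scores = stats::rnorm(L, sd = init_sd),
       labels = labels)
}

crf_path_score <- function(emissions, crf, path_idx) {
  Tlen <- nrow(emissions)
  s <- crf$start_scores[path_idx[1L]] + crf$stop_scores[path_idx[Tlen]]
  s <- s + sum(emissions[cbind(seq_len(Tlen), path_idx)])
  if (Tlen > 1L)
    s <- s + sum(crf$transitions[cbind(path_idx[-Tlen], path_idx[-1L])])
  s
}

crf_forward_logz <- function(emissions, crf) {
  Tlen <- nrow(emissions)
  alpha <- crf$start_scores + emissions[1L, ]
  if (Tlen > 1L) {
    for (t in 2L:Tlen) {
      alpha <- col_log_sum_exp(alpha + crf$transitions) + emissions[t, ]
    }
  }
  log_sum_exp(alpha + crf$stop_scores)
}

#' CRF negative log-likelihood of a gold label sequence
#'
#' @param emissions T x L matrix of per-token label scores.
#' @param crf CRF parameter list from [crf_params()].
#' @param gold_labels Character vector of gold labels (length T).
#' @return Non-negative scalar, `logZ - score(gold)`.
#' @export
crf_neg_log_likelihood <- function(emissions, crf, gold_labels) {
  idx <- match(gold_labels, crf$labels)
  if (anyNA(idx)) stop("gold label outside the CRF label set")
  stopifnot(length(idx) == nrow(emissions))
  if (nrow(emissions) == 0L) return(0)
  crf_forward_logz(emissions, crf) - crf_path_score(emissions, crf, idx)
}

# NLL plus gradients w.r.t. emissions and CRF parameters, via
# forward-backward.  Returns d(NLL)/d(each parameter).
crf_nll_grad <- function(emissions, crf, gold_idx) {
  Tlen <- nrow(emissions)
  L <- length(crf$labels)
  trans <- crf$transitions
  # forward (alpha includes emissions at t), backward (beta excludes them)
  alpha <- matrix(0, Tlen, L)
  alpha[1L, ] <- crf$start_scores + emissions[1L, ]
  if (Tlen > 1L) {
    for (t in 2L:Tlen)
      alpha[t, ] <- col_log_sum_exp(alpha[t - 1L, ] + trans) + emissions[t, ]
  }
  logz <- log_sum_exp(alpha[Tlen, ] + crf$stop_scores)
  beta <- matrix(0, Tlen, L)
  beta[Tlen, ] <- crf$stop_scores
  if (Tlen > 1L) {
    for (t in (Tlen - 1L):1L) {
      # beta[t, from] = LSE_to(trans[from, to] + emit[t+1, to] + beta[t+1, to])
      beta[t, ] <- col_log_sum_exp(t(trans) + (emissions[t + 1L, ] + beta[t + 1L, ]))
    }
  }
  # unary posteriors
  post <- exp(alpha + beta - logz)
  d_emit <- post
  d_emit[cbind(seq_len(Tlen), gold_idx)] <-
    d_emit[cbind(seq_len(Tlen), gold_idx)] - 1
  d_trans <- matrix(0, L, L)
  if (Tlen > 1L) {
    for (t in seq_len(Tlen - 1L)) {
      pair <- outer(alpha[t, ], emissions[t + 1L, ] + beta[t + 1L, ], "+") + trans
      d_trans <- d_trans + exp(pair - logz)
      d_trans[gold_idx[t], gold_idx[t + 1L]] <-
        d_trans[gold_idx[t], gold_idx[t + 1L]] - 1
    }
  }
  d_start <- exp(alpha[1L, ] + beta[1L, ] - logz)
  d_start[gold_idx[1L]] <- d_start[gold_idx[1L]] - 1
  d_stop <- exp(alpha[Tlen, ] + crf$stop_scores - logz)
  d_stop[gold_idx[Tlen]] <- d_stop[gold_idx[Tlen]] - 1
  nll <- logz - crf_path_score(emissions, crf, gold_idx)
  list(nll = nll, d_emissions = d_emit, d_transitions = d_trans,
       d_start = d_start, d_stop = d_stop)
}

#' Viterbi decoding
#'
#' Returns an argmax-scoring label path; ties break toward the lowest
#' label index at every backpointer decision, so decoding is
#' deterministic.
#'
#' @param emissions T x L matrix of label scores.
#' @param crf CRF parameter list.
#' @return Character vector of T labels (empty for T = 0).
#' @export
viterbi_decode <- function(emissions, crf) {
  Tlen <- nrow(emissions)
  if (Tlen == 0L) return(character(0L))
  L <- length(crf$labels)
  delta <- crf$start_scores + emissions[1L, ]
  back <- matrix(0L, Tlen, L)
  if (Tlen > 1L) {
    for (t in 2L:Tlen) {
      scores <- delta + crf$transitions  # [from, to]
      best_from <- apply(scores, 2L, which.max)  # first max = lowest index
      delta <- scores[cbind(best_from, seq_len(L))] + emissions[t, ]
      back[t, ] <- best_from
    }
  }
  final <- delta + crf$stop_scores
  path <- integer(Tlen)
  path[Tlen] <- which.max(final)
  if (Tlen > 1L) {
    for (t in Tlen:2L) path[t - 1L] <- back[t, path[t]]
  }
  crf$labels[path]
}
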