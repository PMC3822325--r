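# Bayesian inference over the learned model: posteriors over symbols or
# disability levels, computed in log space with log-sum-exp
# marginalization so that 15-term products of small probabilities cannot
# underflow.

plog <- function(p) log(pmax(p, 1e-300))

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Discretize a processed trajectory into model evidence
#'
#' @param model an `ew_model`.
#' @param features an `ew_features` (see [process_trajectory()]).
#' @return Object of class `ew_evidence`: list with `vp` (15 x 4 matrix of
#'   domain indices, termination-marker padded), `n_real` (number of
#'   actual via-points), `aux` (named indices), `label`, `disability`.
#' @export
discretize_features <- function(model, features) {
  stopifnot(inherits(model, "ew_model"))
  dvp <- discretize_via_points(features$via, model$config, pad = TRUE)
  structure(
    list(vp = viapoint_indices(dvp, model$domains),
         n_real = min(nrow(features$via), model$config$max_via_points),
         aux = discretize_aux(features$aux, model$domains, model$config),
         label = features$label, disability = features$disability,
         writer = features$writer),
    class = "ew_evidence")
}

# nL x nH matrix of summed log geometric terms for via-points 1..k.
geometry_loglik <- function(model, vp, k) {
  nL <- model$domains$L$size; nH <- model$domains$H$size
  ll <- matrix(0, nL, nH)
  for (dname in c("dx", "dy", "vx", "vy")) {
    v <- vp[, dname]
    ll <- ll + plog(model$tables$first[[dname]][v[1], , ])
    if (k >= 2) for (i in 2:k)
      ll <- ll + plog(model$tables$trans[[dname]][v[i], v[i - 1], i - 1, , ])
  }
  ll
}

aux_letter_loglik <- function(model, aux_idx) {
  plog(model$aux$sx[aux_idx[["sx"]], , ]) +
    plog(model$aux$sy[aux_idx[["sy"]], , ]) +
    plog(model$aux$a[aux_idx[["a"]], , ])
}

new_posterior <- function(domain, prob, k, aux_included) {
  structure(list(domain = domain, prob = prob, k = k,
                 aux_included = aux_included),
            class = "ew_posterior")
}

#' @export
print.ew_posterior <- function(x, ...) {
  top <- sort(x$prob, decreasing = TRUE)[seq_len(min(3, length(x$prob)))]
  cat(sprintf("<ew_posterior> over %s after %s via-point(s)%s; top: %s\n",
              x$domain, x$k, if (x$aux_included) " + aux" else "",
              paste(sprintf("%s=%.3f", names(top), top), collapse = ", ")))
  invisible(x)
}

posterior_from_loglik <- function(model, ll, margin, k, aux_included) {
  if (margin == "L") {
    lp <- apply(ll, 1, logsumexp)
    names(lp) <- model$domains$L$values
  } else {
    lp <- apply(ll, 2, logsumexp)
    names(lp) <- model$domains$H$values
  }
  lp <- lp - max(lp)
  p <- exp(lp); p <- p / sum(p)
  new_posterior(margin, p, k, aux_included)
}

#' Incremental symbol posterior
#'
#' Posterior over symbols given the first `k` via-points, marginalizing
#' the disability level: the online recognition update. The uniform
#' symbol and disability priors cancel into the normalization. With
#' `k = 0` the uniform prior over symbols is returned.
#'
#' @param model an `ew_model`.
#' @param evidence an `ew_evidence` (see [discretize_features()]).
#' @param k number of via-points consumed (default: all real via-points).
#' @return An `ew_posterior` over the symbol domain (including `"$"`).
#' @export
letter_posterior_incremental <- function(model, evidence, k = NULL) {
  stopifnot(inherits(model, "ew_model"), inherits(evidence, "ew_evidence"))
  if (is.null(k)) k <- evidence$n_real
  if (k == 0) {
    p <- model$prior_L
    names(p) <- model$domains$L$values
    return(new_posterior("L", p, 0L, FALSE))
  }
  if (k < 0 || k > model$config$max_via_points)
    stop("letter_posterior_incremental(): k out of range", call. = FALSE)
  ll <- geometry_loglik(model, evidence$vp, k)
  posterior_from_loglik(model, ll, "L", k, FALSE)
}

#' Final symbol posterior with auxiliary variables
#'
#' Posterior over symbols from the complete trajectory: all 15 via-point
#' slots (termination-marker padded beyond the trajectory's end) plus the
#' size and spectral-energy terms inside the disability marginalization.
#' Pupil terms are independent of symbol identity and cancel.
#'
#' @inheritParams letter_posterior_incremental
#' @return An `ew_posterior` over the symbol domain.
#' @export
letter_posterior_final <- function(model, evidence) {
  stopifnot(inherits(model, "ew_model"), inherits(evidence, "ew_evidence"))
  nvp <- model$config$max_via_points
  ll <- geometry_loglik(model, evidence$vp, nvp) +
    aux_letter_loglik(model, evidence$aux)
  posterior_from_loglik(model, ll, "L", nvp, TRUE)
}

#' Novelty posterior and decision
#'
#' Identical computation to [letter_posterior_incremental()] with the
#' unknown-symbol class `"$"` (whose likelihood terms are uniform)
#' competing against the trained symbols. The novelty decision is taken
#' on the geometric posterior *before* auxiliary variables — sizes vary
#' little across an alphabet and would mask novelty — and flags the
#' trajectory as novel when `"$"` is the argmax at trajectory end (an
#' optional minimum-probability threshold can replace the plain argmax
#' rule).
#'
#' @inheritParams letter_posterior_incremental
#' @param min_prob optional minimum posterior probability of `"$"` for a
#'   novelty flag (default `NULL`: plain argmax rule).
#' @return An `ew_posterior` over symbols with attribute `novel`
#'   (logical).
#' @export
novelty_posterior <- function(model, evidence, k = NULL, min_prob = NULL) {
  post <- letter_posterior_incremental(model, evidence, k)
  p_dollar <- post$prob[["$"]]
  novel <- names(post$prob)[which.max(post$prob)] == "$"
  if (!is.null(min_prob)) novel <- novel && p_dollar >= min_prob
  attr(post, "novel") <- novel
  post
}

#' Disability-level posterior
#'
#' Posterior over the disability level from a completed trajectory,
#' marginalizing the symbol: all geometric terms, the size and
#' spectral-energy terms, and the pupil mean/SD terms (which depend on
#' the disability level only).
#'
#' @inheritParams letter_posterior_incremental
#' @return An `ew_posterior` over disability levels 1..3.
#' @export
disability_posterior <- function(model, evidence) {
  stopifnot(inherits(model, "ew_model"), inherits(evidence, "ew_evidence"))
  nvp <- model$config$max_via_points
  ll <- geometry_loglik(model, evidence$vp, nvp) +
    aux_letter_loglik(model, evidence$aux)
  pupil <- plog(model$aux$mup[evidence$aux[["mup"]], ]) +
    plog(model$aux$sigmap[evidence$aux[["sigmap"]], ])
  ll <- sweep(ll, 2, pupil, `+`)
  posterior_from_loglik(model, ll, "H", nvp, TRUE)
}

#' Average disability posterior over a sequence of trajectories
#'
#' For monitoring, the per-trajectory disability posteriors of a session
#' can be averaged into a single distribution.
#'
#' @param model an `ew_model`.
#' @param evidence_list list of `ew_evidence`.
#' @return list with `mean` (averaged posterior vector) and `posteriors`
#'   (matrix, one row per trajectory).
#' @export
assess_disability <- function(model, evidence_list) {
  mat <- t(vapply(evidence_list,
                  function(e) disability_posterior(model, e)$prob,
                  numeric(model$domains$H$size)))
  colnames(mat) <- model$domains$H$values
  list(mean = colMeans(mat), posteriors = mat)
}

#' Shannon entropy of a posterior
#'
#' Concentration measure of a normalized distribution, in nats
#' (`-sum p log p`, with `0 log 0 = 0`).
#'
#' @param posterior an `ew_posterior` or normalized numeric vector.
#' @return Non-negative scalar.
#' @examples
#' shannon_entropy(rep(1 / 36, 36))  # log(36)
#' @export
shannon_entropy <- function(posterior) {
  p <- if (inherits(posterior, "ew_posterior")) posterior$prob else posterior
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-6)
    stop("shannon_entropy(): input is not a normalized distribution",
         call. = FALSE)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Maximum-posterior classification
#'
#' Selects the most probable value; exact ties are broken by domain order
#' and flagged.
#'
#' @param posterior an `ew_posterior`.
#' @return The winning symbol (or level) as a character scalar, with
#'   attribute `tie` (logical).
#' @export
classify <- function(posterior) {
  stopifnot(inherits(posterior, "ew_posterior"))
  p <- posterior$prob
  mx <- max(p)
  winners <- which(p == mx)
  if (length(winners) > 1)
    message("classify(): tie between ",
            paste(names(p)[winners], collapse = ", "),
            "; first in domain order returned")
  structure(names(p)[winners[1]], tie = length(winners) > 1)
}

#' Leave-one-alphabet-out cross-validation
#'
#' Groups exemplars by alphabet (the `writer` metadata), and for each
#' fold trains the model on the remaining alphabets and classifies every
#' held-out character by its final posterior. Accumulates a confusion
#' matrix (rows: presented symbols; columns: recognized symbols including
#' `"$"`) and the mean posterior entropy after each via-point count
#' (position 1 of the entropy curve is the uniform prior, positions
#' 2..16 follow each via-point, the last adds the auxiliary variables).
#'
#' @param features list of labeled `ew_features` with `writer` set.
#' @param config an [ew_config()].
#' @param symbols symbol domain (default: labels present).
#' @return list with `confusion`, `rate` (fraction of correct
#'   recognitions), `n_trials`, `entropy` (mean entropy curve), and
#'   `folds` (alphabet ids).
#' @export
cross_validate <- function(features, config = ew_config(), symbols = NULL) {
  config <- as_ew_config(config)
  writers <- vapply(features, function(f) as.character(f$writer), "")
  labels <- vapply(features, function(f) as.character(f$label), "")
  if (is.null(symbols)) symbols <- sort(unique(labels))
  folds <- sort(unique(writers))
  if (length(folds) < 2)
    stop("cross_validate(): need >= 2 alphabet groups", call. = FALSE)
  all_syms <- sort(unique(c(symbols, "$")))
  confusion <- matrix(0L, length(symbols), length(all_syms),
                      dimnames = list(presented = symbols,
                                      recognized = all_syms))
  nvp <- config$max_via_points
  ent_sum <- numeric(nvp + 2L)
  n_trials <- 0L
  for (w in folds) {
    test_idx <- which(writers == w)
    train_idx <- which(writers != w)
    if (!length(train_idx)) {
      warning("cross_validate(): fold '", w, "' leaves no training data; skipped",
              call. = FALSE)
      next
    }
    model <- learn_model(features[train_idx], config, symbols = symbols)
    for (i in test_idx) {
      ev <- discretize_features(model, features[[i]])
      ent <- numeric(nvp + 2L)
      for (k in 0:nvp)
        ent[k + 1L] <- shannon_entropy(
          letter_posterior_incremental(model, ev, k))
      final <- letter_posterior_final(model, ev)
      ent[nvp + 2L] <- shannon_entropy(final)
      ent_sum <- ent_sum + ent
      guess <- classify(final)
      confusion[labels[i], guess] <- confusion[labels[i], guess] + 1L
      n_trials <- n_trials + 1L
    }
  }
  correct <- sum(confusion[cbind(rownames(confusion),
                                 rownames(confusion))])
  list(confusion = confusion, rate = correct / n_trials,
       n_trials = n_trials, entropy = ent_sum / n_trials, folds = folds)
}
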