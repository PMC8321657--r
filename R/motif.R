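#' Convert a position frequency matrix to probabilities
#'
#' FIMO-style pseudocount: each column of counts receives `pseudocount`
#' distributed by the background frequencies before normalization, so no
#' probability is ever zero.
#'
#' @param pfm L x 4 count matrix (columns A, C, G, T).
#' @param background length-4 background probabilities (sums to 1).
#' @param pseudocount total pseudocount per motif position (default 0.8).
#' @return L x 4 matrix of column probabilities (rows sum to 1).
#' @export
pfm_to_ppm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(ncol(pfm) == 4, abs(sum(background) - 1) < 1e-9)
  tot <- rowSums(pfm)
  ppm <- (pfm + matrix(background * pseudocount, nrow(pfm), 4, byrow = TRUE)) /
    (tot + pseudocount)
  colnames(ppm) <- DNA_BASES
  ppm
}

#' Log-odds position weight matrix (bits)
#' @inheritParams pfm_to_ppm
#' @return L x 4 matrix of log2(ppm/background) scores.
#' @export
pfm_to_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.8) {
  ppm <- pfm_to_ppm(pfm, background, pseudocount)
  sweep(log2(ppm), 2, log2(background), "-")
}

# Exact null distribution of the integer-discretized PWM score under the
# background model, by dynamic programming (convolution over positions).
# Returns the upper-tail probability for every reachable integer score.
pwm_score_tail <- function(int_pwm, background) {
  cur <- NULL
  for (j in seq_len(nrow(int_pwm))) {
    row <- int_pwm[j, ]
    if (is.null(cur)) {
      rng <- range(row)
      cur <- numeric(rng[2] - rng[1] + 1L)
      for (k in 1:4) {
        cur[row[k] - rng[1] + 1L] <- cur[row[k] - rng[1] + 1L] + background[k]
      }
      cur_lo <- rng[1]
    } else {
      new_lo <- cur_lo + min(row)
      new_hi <- cur_lo + length(cur) - 1L + max(row)
      nxt <- numeric(new_hi - new_lo + 1L)
      for (k in 1:4) {
        shift <- cur_lo + row[k] - new_lo
        idx <- seq_along(cur) + shift
        nxt[idx] <- nxt[idx] + background[k] * cur
      }
      cur <- nxt
      cur_lo <- new_lo
    }
  }
  tail_p <- rev(cumsum(rev(cur)))
  list(lo = cur_lo, tail = tail_p)  # P(S >= s) = tail[s - lo + 1]
}

lookup_tail <- function(tail_obj, s_int) {
  i <- s_int - tail_obj$lo + 1L
  n <- length(tail_obj$tail)
  out <- numeric(length(i))
  out[i <= 0] <- 1
  out[i > n] <- 0
  mid <- i >= 1 & i <= n
  out[mid] <- tail_obj$tail[i[mid]]
  out
}

#' Scan a genome for motif instances
#'
#' Both strands are scanned with the log-odds PWM; p-values come from the
#' exact null score distribution under the background model, computed by
#' dynamic programming over scores discretized to 1/1000 bit.  Instances with
#' p-value at or below `p_threshold` are retained.
#'
#' @param genome [read_genome()] result.
#' @param pfms named list of PFMs (from [read_pfms()]), or a single matrix.
#' @param background length-4 background probabilities.
#' @param p_threshold scan p-value cutoff (default 1e-4).
#' @param pseudocount PFM pseudocount (default 0.8).
#' @return Tibble of motif instances: `tf`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `score` (bits), `pval`.
#' @export
scan_motifs <- function(genome, pfms, background = rep(0.25, 4),
                        p_threshold = 1e-4, pseudocount = 0.8) {
  if (is.matrix(pfms)) pfms <- list(motif = pfms)
  codes_by_chrom <- lapply(unclass(genome), dna_codes)
  out <- purrr::imap(pfms, function(pfm, tf) {
    pwm <- pfm_to_pwm(pfm, background, pseudocount)
    L <- nrow(pwm)
    int_pwm <- round(pwm * 1000)
    # reverse-complement PWM: position j reads the complement of position L+1-j
    rc <- function(m) m[L:1, 4:1, drop = FALSE]
    int_rc <- rc(int_pwm)
    pwm_rc <- rc(pwm)
    tails <- pwm_score_tail(int_pwm, background)
    hits <- purrr::imap(codes_by_chrom, function(codes, chrom) {
      n <- length(codes)
      if (n < L) {
        warn(sprintf("Motif %s (%d bp) longer than %s (%d bp); skipped",
                     tf, L, chrom, n))
        return(NULL)
      }
      scan_one <- function(ipwm, fpwm, strand) {
        si <- integer(n - L + 1L)
        sc <- numeric(n - L + 1L)
        ok <- rep(TRUE, n - L + 1L)
        for (j in seq_len(L)) {
          cj <- codes[j:(n - L + j)]
          bad <- is.na(cj)
          ok <- ok & !bad
          cj[bad] <- 1L
          si <- si + ipwm[cbind(j, cj)]
          sc <- sc + fpwm[cbind(j, cj)]
        }
        pv <- lookup_tail(tails, si)
        keep <- ok & pv <= p_threshold
        if (!any(keep)) return(NULL)
        tibble(tf = tf, chrom = chrom, start = which(keep) - 1L,
               end = which(keep) - 1L + L, strand = strand,
               score = sc[keep], pval = pv[keep])
      }
      dplyr::bind_rows(scan_one(int_pwm, pwm, "+"), scan_one(int_rc, pwm_rc, "-"))
    })
    purrr::list_rbind(purrr::compact(hits))
  })
  out <- purrr::list_rbind(purrr::compact(out))
  if (nrow(out) == 0) {
    return(tibble(tf = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(), score = numeric(),
                  pval = numeric()))
  }
  dplyr::arrange(out, .data$tf, .data$chrom, .data$start, .data$strand)
}

#' Keep only top-scoring instances of each TF (Z-score filter)
#'
#' Retains instances whose score lies at least `z_min` population standard
#' deviations above that TF's mean instance score.  When all instances score
#' equally (zero sd) none stands above the mean, so none is kept; a TF with a
#' single instance keeps it (sd undefined).
#'
#' @param instances tibble from [scan_motifs()].
#' @param z_min Z-score cutoff (default 1).
#' @return Filtered instance tibble.
#' @export
zscore_filter <- function(instances, z_min = 1) {
  instances |>
    dplyr::group_by(.data$tf) |>
    dplyr::group_modify(function(g, key) {
      if (nrow(g) < 2) {
        message("TF ", key$tf, ": single instance kept (sd undefined)")
        return(g)
      }
      mu <- mean(g$score)
      sdp <- sqrt(mean((g$score - mu)^2))  # population sd
      if (sdp == 0) return(g[0, ])
      g[g$score >= mu + z_min * sdp, ]
    }) |>
    dplyr::ungroup()
}

#' Motif matching-score change for a substitution
#'
#' The absolute difference between the reference- and alternate-allele
#' probabilities in the motif's probability matrix at the mutated position.
#' On the minus strand the alleles are complemented and the offset mirrored
#' before lookup.
#'
#' @param ppm L x 4 probability matrix ([pfm_to_ppm()]).
#' @param offset 1-based position within the motif in genome orientation.
#' @param ref,alt single-base alleles in genome orientation.
#' @param strand `"+"` or `"-"`.
#' @return Score change in `[0, 1]`.
#' @export
motif_score_change <- function(ppm, offset, ref, alt, strand = "+") {
  if (ref == alt) abort("ref and alt must differ")
  L <- nrow(ppm)
  if (offset < 1 || offset > L) abort("offset outside motif")
  if (strand == "-") {
    offset <- L + 1L - offset
    ref <- complement_base(ref)
    alt <- complement_base(alt)
  }
  unname(abs(ppm[offset, ref] - ppm[offset, alt]))
}

#' Impute a feature value for an unmatched cancer type
#'
#' When no matched cell type carries a feature, the value is imputed from the
#' other cell types: modal label for categorical features, arithmetic mean
#' for numeric ones -- but only when at least `min_cells` cell types have the
#' feature; otherwise the feature stays missing (treated as absent).
#'
#' @param values feature values across available cell types (character or
#'   numeric), `NA`s allowed.
#' @param min_cells minimum number of non-missing cell types (default 4).
#' @return Imputed scalar, or `NA` if too few cell types carry the feature.
#' @export
impute_feature <- function(values, min_cells = 4L) {
  avail <- values[!is.na(values)]
  if (length(avail) < min_cells) {
    return(if (is.numeric(values)) NA_real_ else NA_character_)
  }
  if (is.numeric(avail)) return(mean(avail))
  names(sort(table(avail), decreasing = TRUE))[1]
}

#' Fit annotation weights by logistic regression
#'
#' Trains a logistic model of a binary "functional" label on annotation
#' features and keeps only features with a strictly positive coefficient (a
#' positive log-odds ratio).  On (quasi-)separation the model is refit with a
#' light ridge penalty.
#'
#' @param features data frame of numeric/logical annotation columns.
#' @param label logical or 0/1 functional label, both classes present.
#' @return Object of class `annotation_weights`: a named numeric vector of
#'   positive coefficients, with the full fit in attributes.
#' @export
fit_annotation_weights <- function(features, label) {
  label <- as.integer(label)
  if (length(unique(label)) < 2) abort("Both label classes must be present")
  df <- as.data.frame(lapply(features, as.numeric))
  fit <- suppressWarnings(glm(label ~ ., data = cbind(df, label = label),
                              family = binomial()))
  separated <- !fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  if (separated) {
    message("Separation detected; refitting with ridge penalty")
    X <- as.matrix(df)
    lam <- 1e-2
    b <- ridge_logistic(X, label, lambda = lam)
    co <- b[-1]
    names(co) <- colnames(X)
  } else {
    co <- coef(fit)[-1]
    names(co) <- colnames(df)
  }
  co <- co[!is.na(co)]
  kept <- co[co > 0]
  if (length(kept) == 0) warn("No feature obtained a positive weight")
  structure(kept, class = "annotation_weights",
            all_coefficients = co, separated = separated)
}

# Newton-Raphson ridge-penalized logistic regression (intercept unpenalized).
ridge_logistic <- function(X, y, lambda = 1e-2, maxit = 100) {
  Xi <- cbind(1, X)
  p <- ncol(Xi)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)))
  for (it in seq_len(maxit)) {
    eta <- drop(Xi %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    H <- crossprod(Xi, Xi * W) + pen
    g <- crossprod(Xi, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < 1e-8) break
  }
  beta
}

#' @export
print.annotation_weights <- function(x, ...) {
  cat("<annotation_weights>", length(x), "positive feature(s)\n")
  print(unclass(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy annotation weights
#' @param x `annotation_weights` object.
#' @param ... unused.
#' @return Tibble `feature`, `estimate`, `retained`.
#' @method tidy annotation_weights
#' @export
tidy.annotation_weights <- function(x, ...) {
  all <- attr(x, "all_coefficients")
  tibble(feature = names(all), estimate = unname(all),
         retained = names(all) %in% names(x))
}
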