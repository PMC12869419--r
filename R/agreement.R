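# Double-blind reader-study statistics: trial randomization with pseudo-ID
# blinding, contingency tables, percent agreement (Wilson interval),
# Cohen's kappa (delta-method or bootstrap CI), and a Monte-Carlo power
# check for kappa.

#' Build two blinded trial rosters
#'
#' Each case contributes its real arm to one trial and its synthetic arm
#' to the other (chosen at random per case), so the two arms of one case
#' are never reviewed in the same sitting. Each trial is shuffled
#' independently and renamed with pseudo-IDs; the unblinding key is
#' returned separately.
#'
#' @param cases vector of case ids, or a data.frame with columns `case_id`
#'   and `arm` (both arms required per case)
#' @param seed randomization seed
#' @return list with `trial1`, `trial2` (data.frames pseudo_id, case_id,
#'   arm) and `key` (the unblinding map)
#' @export
build_trials <- function(cases, seed = 1) {
  if (is.data.frame(cases)) {
    tab <- table(cases$case_id, cases$arm)
    need <- c("real", "synthetic")
    if (!all(need %in% colnames(tab)) ||
        any(tab[, need, drop = FALSE] == 0)) {
      bad <- rownames(tab)[rowSums(tab[, intersect(need, colnames(tab)),
                                       drop = FALSE] > 0) < 2]
      stop("case(s) missing an arm: ", paste(bad, collapse = ", "))
    }
    ids <- rownames(tab)
  } else {
    ids <- as.character(cases)
  }
  n <- length(ids)
  with_seed(seed, {
    arm1 <- sample(c("real", "synthetic"), n, replace = TRUE)
    t1 <- data.frame(case_id = ids, arm = arm1)
    t2 <- data.frame(case_id = ids,
                     arm = ifelse(arm1 == "real", "synthetic", "real"))
    t1 <- t1[sample(n), , drop = FALSE]
    t2 <- t2[sample(n), , drop = FALSE]
    t1$pseudo_id <- sprintf("T1-%03d", seq_len(n))
    t2$pseudo_id <- sprintf("T2-%03d", seq_len(n))
    rownames(t1) <- rownames(t2) <- NULL
    key <- rbind(cbind(trial = "trial1", t1[c("pseudo_id", "case_id",
                                              "arm")]),
                 cbind(trial = "trial2", t2[c("pseudo_id", "case_id",
                                              "arm")]))
    list(trial1 = t1[c("pseudo_id", "case_id", "arm")],
         trial2 = t2[c("pseudo_id", "case_id", "arm")],
         key = key)
  })
}

#' Contingency table of paired categorical responses
#'
#' @param a,b paired response vectors (rows = `a`, columns = `b`)
#' @param categories the full codebook; responses outside it are an error;
#'   empty categories are kept
#' @return k x k count matrix
#' @export
contingency <- function(a, b, categories) {
  if (length(a) != length(b)) stop("responses are not paired")
  bad <- setdiff(unique(c(as.character(a), as.character(b))),
                 as.character(categories))
  if (length(bad)) stop("response outside the codebook: ",
                        paste(bad, collapse = ", "))
  fa <- factor(a, levels = categories)
  fb <- factor(b, levels = categories)
  unclass(table(fa, fb, dnn = NULL))
}

#' Percent agreement with a Wilson score interval
#'
#' @param m contingency matrix
#' @param conf confidence level
#' @return list with `estimate` (proportion), `ci`, `n`
#' @export
percent_agreement <- function(m, conf = 0.95) {
  n <- sum(m)
  if (n == 0) stop("empty table")
  p <- sum(diag(m)) / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  list(estimate = p, ci = c(max(0, center - half), min(1, center + half)),
       n = n)
}

kappa_from_matrix <- function(m) {
  n <- sum(m)
  p <- m / n
  po <- sum(diag(p))
  pr <- rowSums(p); pc <- colSums(p)
  pe <- sum(pr * pc)
  if (1 - pe < 1e-12) return(list(kappa = 0, po = po, pe = pe,
                                  degenerate = TRUE))
  list(kappa = (po - pe) / (1 - pe), po = po, pe = pe, degenerate = FALSE)
}

# Fleiss-Cohen-Everitt asymptotic variance of the kappa estimate
kappa_se <- function(m) {
  n <- sum(m)
  p <- m / n
  pr <- rowSums(p); pc <- colSums(p)
  kf <- kappa_from_matrix(m)
  if (kf$degenerate) return(0)
  k <- kf$kappa; pe <- kf$pe
  A <- sum(diag(p) * (1 - (pr + pc) * (1 - k))^2)
  # B term: sum over i != j of p_ij * (p_.i + p_j.)^2
  W <- outer(seq_along(pr), seq_along(pc),
             function(i, j) (pc[i] + pr[j])^2)
  diag(W) <- 0
  B <- (1 - k)^2 * sum(p * W)
  C <- (k - pe * (1 - k))^2
  sqrt(max(0, A + B - C)) / ((1 - pe) * sqrt(n))
}

#' Cohen's kappa with a confidence interval
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with chance agreement `p_e` from the
#' marginal products. Degenerate tables (both raters constant, `p_e = 1`)
#' are defined as kappa 0 with a zero-width interval. The CI is the
#' delta-method asymptotic interval by default, or a seeded case-resampling
#' bootstrap.
#'
#' @param m contingency matrix
#' @param conf confidence level
#' @param ci "asymptotic" or "bootstrap"
#' @param B bootstrap replicates
#' @param seed bootstrap seed
#' @return list with `kappa`, `ci`, `se`, `po`, `pe`, `n`
#' @export
cohens_kappa <- function(m, conf = 0.95, ci = c("asymptotic", "bootstrap"),
                         B = 2000, seed = 1) {
  ci <- match.arg(ci)
  n <- sum(m)
  if (n == 0) stop("empty table")
  kf <- kappa_from_matrix(m)
  if (kf$degenerate) {
    return(list(kappa = 0, ci = c(0, 0), se = 0, po = kf$po, pe = kf$pe,
                n = n))
  }
  if (ci == "asymptotic") {
    se <- kappa_se(m)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    interval <- c(max(-1, kf$kappa - z * se), min(1, kf$kappa + z * se))
  } else {
    k <- nrow(m)
    idx <- cbind(rep(seq_len(k), k), rep(seq_len(k), each = k))
    pairs <- idx[rep(seq_len(nrow(idx)), as.vector(m)), , drop = FALSE]
    boots <- with_seed(seed, vapply(seq_len(B), function(b) {
      take <- pairs[sample.int(n, n, replace = TRUE), , drop = FALSE]
      mb <- matrix(0, k, k)
      for (r in seq_len(nrow(take))) {
        mb[take[r, 1], take[r, 2]] <- mb[take[r, 1], take[r, 2]] + 1
      }
      kappa_from_matrix(mb)$kappa
    }, numeric(1)))
    se <- stats::sd(boots)
    interval <- unname(stats::quantile(boots,
                                       c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  list(kappa = kf$kappa, ci = interval, se = se, po = kf$po, pe = kf$pe,
       n = n)
}

# Fleiss null-hypothesis (kappa = 0) standard error, used by the power
# simulation's z-test
kappa_se_null <- function(m) {
  n <- sum(m)
  p <- m / n
  pr <- rowSums(p); pc <- colSums(p)
  pe <- sum(pr * pc)
  if (1 - pe < 1e-12) return(0)
  v <- (pe + pe^2 - sum(pr * pc * (pr + pc))) / (n * (1 - pe)^2)
  sqrt(max(0, v))
}

#' Monte-Carlo power of the kappa z-test
#'
#' Simulates paired categorical responses with the stated common marginals
#' and population kappa (`P = (1 - kappa) p p' + kappa diag(p)`), tests
#' `kappa = 0` with the Fleiss z-test at level `alpha`, and reports the
#' rejection fraction.
#'
#' @param true_kappa population kappa (must be compatible with the
#'   marginals: all joint probabilities nonnegative)
#' @param marginals category probabilities (common to both raters)
#' @param n pairs per simulated study
#' @param alpha significance level (two-sided)
#' @param reps Monte-Carlo replicates (>= 1000)
#' @param seed simulation seed
#' @return power estimate (fraction of rejections)
#' @export
kappa_power <- function(true_kappa, marginals, n, alpha = 0.05,
                        reps = 2000, seed = 1) {
  if (reps < 1000) stop("reps must be at least 1000")
  if (abs(sum(marginals) - 1) > 1e-8) stop("marginals must sum to 1")
  k <- length(marginals)
  P <- (1 - true_kappa) * outer(marginals, marginals) +
    true_kappa * diag(marginals, k)
  if (min(P) < -1e-12) stop("true_kappa incompatible with the marginals")
  P <- pmax(P, 0)
  zcrit <- stats::qnorm(1 - alpha / 2)
  with_seed(seed, {
    rejections <- vapply(seq_len(reps), function(r) {
      cnt <- stats::rmultinom(1, n, as.vector(P))
      m <- matrix(cnt, k, k)
      kf <- kappa_from_matrix(m)
      se0 <- kappa_se_null(m)
      if (se0 == 0) return(FALSE)
      abs(kf$kappa / se0) > zcrit
    }, logical(1))
    mean(rejections)
  })
}
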