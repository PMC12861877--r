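#' The twin transform pair
#'
#' Produces the two branch inputs from one source patch: the plus branch is
#' the identity copy, the minus branch is the horizontal mirror. Both are
#' label-preserving for texture and the mirror is an involution, so the
#' pair is cheap to verify and genuinely distinct at the pixel level.
#'
#' @param x image/patch matrix.
#' @return object of class `octx_twinpair`: list with `x_plus`, `x_minus`.
#' @export
twin_transform <- function(x) {
  stopifnot(is.matrix(x), length(x) > 0)
  structure(list(x_plus = x, x_minus = x[, rev(seq_len(ncol(x))), drop = FALSE]),
            class = "octx_twinpair")
}

four_classes <- c("P+", "P-", "N+", "N-")

#' Map a binary label and branch to the four-class scheme
#'
#' `(P, plus) -> P+`, `(P, minus) -> P-`, `(N, plus) -> N+`,
#' `(N, minus) -> N-`.
#'
#' @param label `"P"` or `"N"`.
#' @param branch `"plus"` or `"minus"`.
#' @return one of `"P+"`, `"P-"`, `"N+"`, `"N-"`.
#' @export
map_to_four_class <- function(label, branch = c("plus", "minus")) {
  branch <- match.arg(branch)
  if (!label %in% c("P", "N")) stop("label must be 'P' or 'N'")
  paste0(label, if (branch == "plus") "+" else "-")
}

#' Fuse the twin four-class posteriors into a binary decision
#'
#' Given the plus-branch posterior `theta` and the minus-branch posterior
#' `psi` over `{P+, P-, N+, N-}`, the decision rule is:
#' \itemize{
#'   \item if `argmax theta = N+` and `argmax psi = N-`: label `N`;
#'   \item if `argmax theta = P+` and `argmax psi = P-`: label `P`;
#'   \item otherwise: `N` iff the largest N-group entry across both
#'     posteriors exceeds the largest P-group entry, else `P` (ties to P).
#' }
#' The confidence is `m_win / (m_P + m_N)` where `m_P`, `m_N` are the two
#' group maxima — the reliability of the winning group.
#'
#' @param theta,psi numeric length-4 posteriors in the order
#'   `P+, P-, N+, N-`, each summing to 1 (tolerance 1e-6).
#' @return object of class `octx_decision`: list with `label` (`"P"` or
#'   `"N"`), `confidence`, `rule_branch` (`"agree_N"`, `"agree_P"`,
#'   `"otherwise"`).
#' @export
fuse_twin_posteriors <- function(theta, psi) {
  for (v in list(theta, psi)) {
    if (length(v) != 4 || any(v < -1e-12) || abs(sum(v) - 1) > 1e-6)
      stop("posterior must be 4 non-negative probabilities summing to 1")
  }
  theta <- stats::setNames(as.numeric(theta), four_classes)
  psi <- stats::setNames(as.numeric(psi), four_classes)
  am_t <- four_classes[which.max(theta)]
  am_p <- four_classes[which.max(psi)]
  m_p <- max(theta[c("P+", "P-")], psi[c("P+", "P-")])
  m_n <- max(theta[c("N+", "N-")], psi[c("N+", "N-")])
  if (am_t == "N+" && am_p == "N-") {
    label <- "N"; branch <- "agree_N"
  } else if (am_t == "P+" && am_p == "P-") {
    label <- "P"; branch <- "agree_P"
  } else {
    label <- if (m_n > m_p) "N" else "P"
    branch <- "otherwise"
  }
  m_win <- if (label == "P") m_p else m_n
  structure(list(label = label, confidence = m_win / (m_p + m_n),
                 rule_branch = branch),
            class = "octx_decision")
}

#' @export
print.octx_decision <- function(x, ...) {
  cat(sprintf("<octx_decision> %s (confidence %.3f, %s)\n",
              x$label, x$confidence, x$rule_branch))
  invisible(x)
}

#' Fuse a matrix of twin posteriors row-wise
#'
#' @param theta_mat,psi_mat matrices `n x 4` of plus/minus posteriors.
#' @return data.frame with `label`, `confidence`, `rule_branch` and a
#'   `score` column (confidence folded toward P: `confidence` if the label
#'   is P, `1 - confidence` otherwise), usable for ROC analysis.
#' @export
fuse_twin_matrix <- function(theta_mat, psi_mat) {
  stopifnot(nrow(theta_mat) == nrow(psi_mat))
  out <- lapply(seq_len(nrow(theta_mat)), function(i)
    fuse_twin_posteriors(theta_mat[i, ], psi_mat[i, ]))
  lab <- vapply(out, `[[`, "", "label")
  conf <- vapply(out, `[[`, 0, "confidence")
  data.frame(label = lab, confidence = conf,
             rule_branch = vapply(out, `[[`, "", "rule_branch"),
             score = ifelse(lab == "P", conf, 1 - conf),
             stringsAsFactors = FALSE)
}
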