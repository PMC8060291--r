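#' Tissue deconvolution by constrained least squares
#'
#' Estimates the fractional tissue contributions to each cfRNA sample by
#' solving, per sample,
#' \deqn{\min_\beta \|X\beta - y\|^2 \quad s.t. \quad \beta_i \ge 0,\;
#'   \sum_i \beta_i \le 1,}
#' where `y` is the sample's RPM over the signature genes and `X` is the
#' genes-by-tissues median-expression signature. The unexplained portion
#' `1 - sum(beta)` is reported as the *remainder* (tissues absent from the
#' signature). The quadratic program is solved with [quadprog::solve.QP()]
#' on `D = X'X` (with a `1e-10` ridge on the diagonal if `X'X` is singular,
#' e.g. collinear signatures). Deconvolution operates on RPM directly -- the
#' mixing model is linear in abundance, so no log transform is applied.
#'
#' Signature genes absent from `expr` are dropped from both `y` and `X` with
#' a warning; a sample with all-zero expression over the signature genes gets
#' `beta = 0` and remainder 1.
#'
#' @param expr Expression tibble in RPM (`gene` column plus one column per
#'   sample), or a named numeric vector over genes for a single sample.
#' @param signature A `tissue_signature` from [select_signature_genes()].
#'
#' @return A tibble of class `deconvolution_result`: one row per sample with
#'   columns `sample_id`, one fraction column per tissue, `remainder` and
#'   `residual` (the residual norm `||X beta - y||`).
#' @export
deconvolve <- function(expr, signature) {
  stopifnot(inherits(signature, "tissue_signature"))
  if (is.numeric(expr) && !is.null(names(expr))) {
    expr <- dplyr::bind_cols(tibble::tibble(gene = names(expr)),
                             tibble::tibble(sample = unname(expr)))
  }
  m <- as_gene_matrix(expr, "expr")
  genes <- intersect(signature$genes, rownames(m))
  missing <- setdiff(signature$genes, rownames(m))
  if (!length(genes)) abort("none of the signature genes are present in `expr`.")
  if (length(missing)) {
    warn(sprintf("%d signature gene(s) absent from `expr` were dropped.",
                 length(missing)))
  }
  X <- signature$X[genes, , drop = FALSE]
  if (all(X == 0)) abort("signature matrix is all zero over the available genes.")

  res <- purrr::map(colnames(m), function(s) {
    y <- m[genes, s]
    fit <- solve_fraction_qp(X, y)
    tibble::tibble(
      sample_id = s,
      !!!setNames(as.list(fit$beta), colnames(X)),
      remainder = 1 - sum(fit$beta),
      residual = fit$residual
    )
  }) |> purrr::list_rbind()
  class(res) <- c("deconvolution_result", class(res))
  attr(res, "tissues") <- colnames(X)
  attr(res, "n_genes") <- length(genes)
  res
}

# min 1/2 b' (X'X) b - (X'y)' b  s.t.  b >= 0, sum(b) <= 1
solve_fraction_qp <- function(X, y) {
  p <- ncol(X)
  if (all(y == 0)) {
    return(list(beta = setNames(rep(0, p), colnames(X)), residual = 0))
  }
  D <- crossprod(X)
  if (inherits(try(chol(D), silent = TRUE), "try-error")) {
    D <- D + diag(1e-10, p)
  }
  d <- crossprod(X, y)
  Amat <- cbind(diag(p), -rep(1, p))
  bvec <- c(rep(0, p), -1)
  sol <- quadprog::solve.QP(D, d, Amat, bvec)
  beta <- setNames(sol$solution, colnames(X))
  list(beta = beta, residual = sqrt(sum((X %*% beta - y)^2)))
}

#' @export
#' @rdname deconvolve
#' @param x A `deconvolution_result`.
#' @param ... Unused.
tidy.deconvolution_result <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x),
                      cols = dplyr::all_of(attr(x, "tissues")),
                      names_to = "tissue", values_to = "fraction")
}

#' Stacked tissue-fraction plot
#'
#' @param object A `deconvolution_result` from [deconvolve()].
#' @param ... Unused.
#' @return A ggplot object: one stacked bar of tissue fractions (plus the
#'   remainder) per sample.
#' @export
autoplot.deconvolution_result <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(cols = c(dplyr::all_of(attr(object, "tissues")), "remainder"),
                        names_to = "tissue", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$fraction,
                                     fill = .data$tissue)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "estimated fraction", fill = "tissue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
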