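#' Genomic relationship kernels
#'
#' `vanraden_kernel()` builds the additive genomic relationship matrix
#' \deqn{K = c^{-1} (M - P)(M - P)^T + \mathrm{nugget} \cdot I}
#' where, for \{0,1,2\}-coded minor-allele counts, \eqn{P = 1_n \otimes 2 p^T}
#' and \eqn{c = 2 p^T (1 - p)} with \eqn{p} the allele-frequency vector. For
#' boolean-coded inbred scores (\{0,1\}) the inbred analogue is used: columns
#' are centered by their means \eqn{\bar p} and \eqn{c = \sum \bar p (1 - \bar
#' p)}; set `double_inbred = TRUE` to instead double the scores to \{0,2\} and
#' apply the diploid formula literally. Real-valued (structure-deflated) scores
#' use the column-mean centering path. The small ridge on the diagonal (0.01 by
#' default) restores full rank after centering so the kernel is invertible.
#'
#' When `p` is estimated from the marker set itself, centering forces every row
#' of the additive kernel to sum to the nugget.
#'
#' @param marker_set A complete (imputed) [marker_set()].
#' @param p Optional allele-frequency vector (one entry per marker) to center
#'   with; defaults to frequencies estimated from the score matrix.
#' @param nugget Ridge added to the diagonal; 0.01 by default for additive
#'   kernels, use 0 when the kernel is a component of a product.
#' @param double_inbred With `"01"` coding, double scores to \{0,2\} and apply
#'   the \{0,1,2\} formula as-is.
#' @param label Term label recorded on the kernel (`"G"`, `"A"`, ...).
#' @return A `genetic_kernel`: an n-by-n symmetric matrix with attributes
#'   `label`, `c` (the scaling constant) and `nugget`.
#' @export
vanraden_kernel <- function(marker_set, p = NULL, nugget = 0.01,
                            double_inbred = FALSE, label = "G") {
  cw <- center_scores(marker_set, p = p, double_inbred = double_inbred)
  K <- tcrossprod(cw$W) / cw$c
  if (nugget != 0) diag(K) <- diag(K) + nugget
  new_genetic_kernel(K, label = label, c = cw$c, nugget = nugget)
}

# Centered score matrix W = M - P and scaling constant c for a marker set.
# {0,1,2}: P = 1 (x) 2p', c = 2 p'(1-p); {0,1}/real: column-mean centering with
# c = sum(pbar (1-pbar)) (the inbred analogue).
center_scores <- function(marker_set, p = NULL, double_inbred = FALSE) {
  x <- marker_set
  if (anyNA(x$scores)) stop("Impute missing scores before building kernels.",
                            call. = FALSE)
  if (n_markers(x) == 0) stop("No markers.", call. = FALSE)
  M <- x$scores
  coding <- x$coding
  if (coding == "01" && double_inbred) {
    M <- 2 * M
    coding <- "012"
  }
  if (coding == "012") {
    if (is.null(p)) p <- colMeans(M) / 2
    ctr <- 2 * p
    cc <- 2 * sum(p * (1 - p))
  } else {
    if (is.null(p)) p <- colMeans(M)
    ctr <- p
    cc <- sum(p * (1 - p))
  }
  if (cc <= 0) {
    stop("Scaling constant c = 0: all markers monomorphic under the supplied ",
         "frequencies.", call. = FALSE)
  }
  list(W = sweep(M, 2, ctr, "-"), c = cc)
}

new_genetic_kernel <- function(values, label, c, nugget) {
  values <- (values + t(values)) / 2  # enforce exact symmetry
  structure(values, class = c("genetic_kernel", "matrix", "array"),
            label = label, c = c, nugget = nugget)
}

#' @export
print.genetic_kernel <- function(x, ...) {
  cat("<genetic_kernel> ", kernel_label(x), ": ", nrow(x), " x ", ncol(x),
      ", c = ", format(kernel_c(x), digits = 6),
      ", nugget = ", kernel_nugget(x), "\n", sep = "")
  k <- min(5L, nrow(x))
  print(unclass(x)[seq_len(k), seq_len(k), drop = FALSE], digits = 4)
  if (nrow(x) > k) cat("  ... (", nrow(x) - k, " more lines)\n", sep = "")
  invisible(x)
}

#' @rdname vanraden_kernel
#' @param kernel A `genetic_kernel`.
#' @export
kernel_label <- function(kernel) attr(kernel, "label")

#' @rdname vanraden_kernel
#' @export
kernel_c <- function(kernel) attr(kernel, "c")

#' @rdname vanraden_kernel
#' @export
kernel_nugget <- function(kernel) attr(kernel, "nugget")

#' Add a ridge to a kernel's diagonal
#'
#' @param kernel A `genetic_kernel`.
#' @param nugget Amount to add to every diagonal entry.
#' @return The ridged kernel; the `nugget` attribute accumulates.
#' @export
add_nugget <- function(kernel, nugget = 0.01) {
  v <- unclass(kernel)
  diag(v) <- diag(v) + nugget
  new_genetic_kernel(v, label = kernel_label(kernel), c = kernel_c(kernel),
                     nugget = kernel_nugget(kernel) + nugget)
}

#' Per-subgenome additive kernels
#'
#' Builds one additive relationship kernel per subgenome, each from only the
#' markers assigned to that subgenome, with its own allele frequencies and
#' scaling constant. With `nugget = 0` the kernels satisfy the exact partition
#' identity \eqn{c_G K_G = \sum_g c_g K_g}.
#'
#' @param marker_set A complete [marker_set()] with subgenomes assigned.
#' @param nugget Ridge per kernel (default 0: subgenome kernels are usually
#'   combined into products first and ridged at model time).
#' @param subgenomes Subgenome labels that must each be represented.
#' @inheritParams vanraden_kernel
#' @return Named list of `genetic_kernel`s, one per subgenome.
#' @export
subgenome_kernels <- function(marker_set, nugget = 0,
                              subgenomes = c("A", "B", "D"),
                              double_inbred = FALSE) {
  x <- marker_set
  if (is.null(x$subgenome)) stop("Assign subgenomes first.", call. = FALSE)
  out <- list()
  for (g in subgenomes) {
    j <- which(x$subgenome == g)
    if (!length(j)) stop("Subgenome ", g, " has no markers.", call. = FALSE)
    out[[g]] <- vanraden_kernel(subset_markers(x, j), nugget = nugget,
                                double_inbred = double_inbred, label = g)
  }
  out
}

#' Additive-by-additive epistatic kernel
#'
#' The exact epistatic relationship matrix of the whole genome is
#' \deqn{H = K \circ K - c^{-2} (W \circ W)(W \circ W)^T}
#' where \eqn{K} is the nugget-free additive kernel, \eqn{W} the centered score
#' matrix, \eqn{c} the additive scaling constant and \eqn{\circ} the
#' element-wise product. The second term removes the squared self-pairs, so
#' \eqn{H} equals \eqn{2 c^{-2} E E^T} with \eqn{E}'s columns the element-wise
#' products of all distinct marker pairs. With `exact = FALSE` the large-m
#' approximation \eqn{H = K \circ K} is returned.
#'
#' @inheritParams vanraden_kernel
#' @param exact Subtract the self-pair correction (default `TRUE`).
#' @return A `genetic_kernel` labelled `"I"` (nugget-free).
#' @export
epistatic_kernel <- function(marker_set, exact = TRUE, p = NULL,
                             double_inbred = FALSE) {
  if (n_markers(marker_set) == 0) stop("No markers.", call. = FALSE)
  cw <- center_scores(marker_set, p = p, double_inbred = double_inbred)
  K0 <- tcrossprod(cw$W) / cw$c
  H <- K0 * K0
  if (exact) {
    W2 <- cw$W * cw$W
    H <- H - tcrossprod(W2) / cw$c^2
  }
  new_genetic_kernel(H, label = "I", c = cw$c^2, nugget = 0)
}

#' Inter-subgenome interaction kernel (Hadamard product)
#'
#' The covariance of additive-by-additive interactions between disjoint marker
#' sets (e.g. two subgenomes of an allopolyploid) is the Hadamard product of
#' the component additive kernels, \eqn{K_A \circ K_B}; the three-way product
#' \eqn{K_A \circ K_B \circ K_D} captures the three-subgenome interaction.
#' Components must be nugget-free and share the same lines in the same order
#' (no silent reordering is attempted).
#'
#' @param ... Two or three `genetic_kernel`s (or a single list of them).
#' @return A `genetic_kernel` labelled by the concatenated component labels,
#'   with `c` the product of the component constants.
#' @export
interaction_kernel <- function(...) {
  ks <- list(...)
  if (length(ks) == 1 && is.list(ks[[1]]) && !inherits(ks[[1]], "genetic_kernel")) {
    ks <- ks[[1]]
  }
  if (length(ks) < 2 || length(ks) > 3) {
    stop("Supply 2 or 3 component kernels.", call. = FALSE)
  }
  ids <- lapply(ks, rownames)
  if (any(vapply(ids, is.null, logical(1)))) {
    stop("Component kernels must carry line IDs.", call. = FALSE)
  }
  for (i in 2:length(ks)) {
    if (!identical(ids[[1]], ids[[i]])) {
      stop("Component kernels have mismatched line orderings.", call. = FALSE)
    }
  }
  nug <- vapply(ks, kernel_nugget, double(1))
  if (any(nug != 0)) {
    stop("Interaction components must be built without a nugget.", call. = FALSE)
  }
  v <- Reduce(`*`, lapply(ks, unclass))
  new_genetic_kernel(v,
                     label = paste0(vapply(ks, kernel_label, character(1)),
                                    collapse = ""),
                     c = prod(vapply(ks, kernel_c, double(1))),
                     nugget = 0)
}

#' Build the kernel set for a named model
#'
#' Convenience constructor for the four model families: `"G"` (whole-genome
#' additive), `"ABD"` (subgenome additive), `"GxG"` (whole genome plus
#' epistasis) and `"ABDxABD"` (subgenome additive plus pairwise inter-subgenome
#' interactions, optionally the three-way term). Products are formed from
#' nugget-free components; every returned kernel then receives its own ridge so
#' the model covariance is invertible.
#'
#' @inheritParams vanraden_kernel
#' @param model One of `"G"`, `"ABD"`, `"GxG"`, `"ABDxABD"`.
#' @param exact_h Use the exact epistatic kernel in `"GxG"`.
#' @param three_way Include the `ABD` three-way interaction kernel in
#'   `"ABDxABD"`. Off by default: this component is routinely estimated on the
#'   zero boundary and can be dropped without changing the fit.
#' @return Named list of ridged `genetic_kernel`s, ready for [model_spec()].
#' @export
build_kernels <- function(marker_set, model = c("G", "ABD", "GxG", "ABDxABD"),
                          nugget = 0.01, exact_h = TRUE, three_way = FALSE,
                          double_inbred = FALSE) {
  model <- match.arg(model)
  if (model == "G") {
    return(list(G = vanraden_kernel(marker_set, nugget = nugget,
                                    double_inbred = double_inbred)))
  }
  if (model == "GxG") {
    H <- epistatic_kernel(marker_set, exact = exact_h, double_inbred = double_inbred)
    return(list(G = vanraden_kernel(marker_set, nugget = nugget,
                                    double_inbred = double_inbred),
                I = add_nugget(H, nugget)))
  }
  base <- subgenome_kernels(marker_set, nugget = 0, double_inbred = double_inbred)
  out <- lapply(base, add_nugget, nugget = nugget)
  if (model == "ABDxABD") {
    pairs <- utils::combn(names(base), 2, simplify = FALSE)
    for (pr in pairs) {
      out[[paste0(pr, collapse = "")]] <-
        add_nugget(interaction_kernel(base[pr]), nugget)
    }
    if (three_way && length(base) == 3) {
      out[[paste0(names(base), collapse = "")]] <-
        add_nugget(interaction_kernel(base), nugget)
    }
  }
  out
}

#' Tidy a genetic kernel into a long tibble
#'
#' @param x A `genetic_kernel`.
#' @param ... Unused.
#' @return Tibble with columns `line_1`, `line_2`, `value`, `term`.
#' @export
tidy.genetic_kernel <- function(x, ...) {
  v <- unclass(x)
  tibble::tibble(
    line_1 = rep(rownames(v), times = ncol(v)),
    line_2 = rep(colnames(v), each = nrow(v)),
    value = as.vector(v),
    term = kernel_label(x)
  )
}
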