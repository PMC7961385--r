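## SMOTE minority-class oversampling.

#' SMOTE: synthetic minority oversampling
#'
#' Equalizes all class counts to the majority count. Each synthetic instance
#' is built by picking a random minority instance x, one of its k nearest
#' same-class neighbours x_nn (Euclidean distance in the flattened feature
#' space), and emitting `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)` — a
#' random point on the segment between the two. Original instances are
#' returned unchanged, with the synthetic ones appended after them.
#'
#' @param x numeric matrix n x d of flattened instances
#' @param labels vector of class labels, length n
#' @param k number of nearest neighbours (default 5); reduced with a warning
#'   for classes with k or fewer members; classes of size 1 are an error
#' @param rng_seed integer seed
#' @return list with `x` (resampled matrix), `labels`, and `synthetic`
#'   (logical vector marking appended rows)
#' @export
smote <- function(x, labels, k = 5, rng_seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  counts <- table(labels)
  n_major <- max(counts)
  new_x <- list(); new_y <- list()
  with_seed(rng_seed, {
    for (cls in names(counts)) {
      n_c <- counts[[cls]]
      need <- n_major - n_c
      if (need == 0) next
      if (n_c == 1) stop("class '", cls, "' has a single instance; ",
                         "SMOTE needs at least 2")
      k_c <- k
      if (n_c <= k) {
        k_c <- n_c - 1
        warning("class '", cls, "' has only ", n_c,
                " members; reducing k to ", k_c)
      }
      idx <- which(labels == cls)
      xc <- x[idx, , drop = FALSE]
      nn <- knn_index(xc, k_c)
      parents <- sample.int(n_c, need, replace = TRUE)
      pick <- sample.int(k_c, need, replace = TRUE)
      u <- runif(need)
      a <- xc[parents, , drop = FALSE]
      b <- xc[nn[cbind(parents, pick)], , drop = FALSE]
      new_x[[cls]] <- a + u * (b - a)
      new_y[[cls]] <- rep(if (is.numeric(labels)) as.numeric(cls) else cls,
                          need)
    }
  })
  if (length(new_x)) {
    syn_x <- do.call(rbind, new_x)
    syn_y <- unlist(new_y, use.names = FALSE)
    if (is.integer(labels)) syn_y <- as.integer(syn_y)
    list(x = rbind(x, syn_x), labels = c(labels, syn_y),
         synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(syn_x))))
  } else {
    list(x = x, labels = labels, synthetic = rep(FALSE, nrow(x)))
  }
}

# k nearest same-set neighbours (excluding self) via the squared-distance
# Gram-matrix identity; returns an n x k index matrix
knn_index <- function(x, k) {
  n <- nrow(x)
  g <- tcrossprod(x)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  diag(d2) <- Inf
  res <- apply(d2, 1, function(row) order(row)[seq_len(k)])
  if (k == 1) matrix(res, ncol = 1) else t(res)
}
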