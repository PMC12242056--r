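# Evaluation metrics for generated images: the CAT (category-based
# assessment table) tag-match score on its 1000-point scale, and the Frechet
# distance between feature distributions with a pluggable extractor.

#' Tag matches of one generated image against its card
#'
#' Counts how many of the card's 5 slots (broad_1, broad_2, specific,
#' background, attribute) have their tag present in `generated_tags`, by
#' exact string equality after lowercase/trim normalization. Each slot scores
#' at most 1 point.
#'
#' @param generated_tags Character vector/set of tags describing the
#'   generated image.
#' @param card One tag card (a row of [make_tag_cards()], or any list with
#'   the 5 slot fields).
#' @return Integer in 0..5.
#' @examples
#' card <- list(broad_1 = "animal", broad_2 = "mammal", specific = "cat",
#'              background = "indoor", attribute = "furry")
#' match_tags(c("animal", "cat", "outdoor"), card) # 2
#' @export
match_tags <- function(generated_tags, card) {
  validate_tag_card(card)
  gen <- normalize_tag(as.character(generated_tags))
  slots <- c("broad_1", "broad_2", "specific", "background", "attribute")
  sum(vapply(slots, function(s) normalize_tag(card[[s]]) %in% gen, logical(1)))
}

#' CAT score of a generated image set
#'
#' Sums per-image tag matches over aligned (generated tags, card) pairs.
#' With the 200-image reference test set the maximum is 200 x 5 = 1000
#' points.
#'
#' @param all_generated_tags Named list of character vectors; names (or an
#'   `image_id` attribute order) align with `cards$image_id`.
#' @param cards Tag cards ([make_tag_cards()]).
#' @return Object of class `cat_result`: `per_image_points`, `total`,
#'   `max_possible`, `image_id`.
#' @export
cat_score <- function(all_generated_tags, cards) {
  if (length(all_generated_tags) != nrow(cards)) {
    stop_arg("need one generated tag set per card (", nrow(cards), ")")
  }
  ids <- names(all_generated_tags)
  if (!is.null(ids)) {
    ord <- match(as.character(cards$image_id), ids)
    if (anyNA(ord)) {
      stop_arg("generated tags and cards are misaligned: missing image_id ",
               cards$image_id[which(is.na(ord))[1L]])
    }
    all_generated_tags <- all_generated_tags[ord]
  }
  pts <- vapply(seq_len(nrow(cards)), function(i) {
    match_tags(all_generated_tags[[i]], as.list(cards[i, , drop = FALSE]))
  }, numeric(1))
  structure(
    list(per_image_points = as.integer(pts), total = as.integer(sum(pts)),
         max_possible = 5L * nrow(cards), image_id = cards$image_id),
    class = "cat_result"
  )
}

#' @export
print.cat_result <- function(x, ...) {
  cat(sprintf("CAT score: %d / %d points over %d images (mean %.2f tags/image)\n",
              x$total, x$max_possible, length(x$per_image_points),
              mean(x$per_image_points)))
  invisible(x)
}

# symmetric PSD square root via eigendecomposition, negative eigenvalues
# clipped at -1e-10 (larger deficits raise an error)
psd_sqrt_trace <- function(S_r, S_g) {
  er <- eigen((S_r + t(S_r)) / 2, symmetric = TRUE)
  sq <- er$vectors %*% (sqrt(pmax(er$values, 0)) * t(er$vectors))
  M <- sq %*% S_g %*% sq
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(1, abs(ev[1L])))) {
    ev <- pmax(ev, 0)
  }
  sum(sqrt(pmax(ev, 0)))
}

#' Frechet distance between two feature distributions
#'
#' `||mu_r - mu_g||^2 + Tr(S_r + S_g - 2 (S_r S_g)^{1/2})` with sample
#' covariances (1/(n-1)); the matrix square root is computed from the
#' symmetrized eigendecomposition with small negative eigenvalues clipped.
#' Identical feature sets score 0; lower is better.
#'
#' @param features_real Matrix `N x F` of reference features.
#' @param features_gen Matrix `M x F` of generated features.
#' @return Object of class `fid_result`: `value`, `n_real`, `n_gen`,
#'   `feature_dim`.
#' @examples
#' x <- matrix(rnorm(200), 50)
#' fid(x, x)$value # 0
#' @export
fid <- function(features_real, features_gen) {
  X <- as.matrix(features_real)
  Y <- as.matrix(features_gen)
  if (ncol(X) != ncol(Y)) stop_arg("feature dimensions differ")
  assert_finite(X, "features_real")
  assert_finite(Y, "features_gen")
  F <- ncol(X)
  if (nrow(X) < F + 1 || nrow(Y) < F + 1) {
    warning("fewer samples than feature_dim + 1; covariance estimates are singular")
  }
  mu_r <- colMeans(X)
  mu_g <- colMeans(Y)
  S_r <- if (nrow(X) > 1) stats::cov(X) else matrix(0, F, F)
  S_g <- if (nrow(Y) > 1) stats::cov(Y) else matrix(0, F, F)
  val <- sum((mu_r - mu_g)^2) + sum(diag(S_r)) + sum(diag(S_g)) -
    2 * psd_sqrt_trace(S_r, S_g)
  structure(
    list(value = max(val, 0), n_real = nrow(X), n_gen = nrow(Y),
         feature_dim = F),
    class = "fid_result"
  )
}

#' @export
print.fid_result <- function(x, ...) {
  cat(sprintf("Frechet distance: %.4f (n_real = %d, n_gen = %d, dim = %d)\n",
              x$value, x$n_real, x$n_gen, x$feature_dim))
  invisible(x)
}

#' Toy image decoder
#'
#' A fixed random linear map from embedding space to a small pixel grid,
#' squashed into [0, 1]. It stands in for the latent-diffusion image
#' generator so that the full two-stage pipeline (embedding -> image ->
#' features -> Frechet distance) is exercisable at desk scale; it is
#' synthetic plumbing, not a learned generator.
#'
#' @param embed_dim Embedding width it accepts.
#' @param height,width Output image size.
#' @param seed Seed fixing the decoder weights.
#' @return Object of class `toy_decoder`.
#' @export
toy_decoder <- function(embed_dim, height = 8, width = 8, seed = 1) {
  W <- with_seed(seed, matrix(stats::rnorm(embed_dim * height * width,
                                           sd = 1 / sqrt(embed_dim)),
                              embed_dim))
  structure(list(W = W, embed_dim = embed_dim, height = height, width = width,
                 seed = seed),
            class = "toy_decoder")
}

#' Generate a toy image and its feature vector from an embedding
#'
#' Deterministic given (embedding, decoder): the image is the decoder's
#' sigmoid-squashed linear map; the feature vector is the embedding itself
#' (identity extractor), which makes the Frechet distance on features
#' directly comparable across pipeline stages.
#'
#' @param embedding Numeric vector of length `decoder$embed_dim`.
#' @param decoder A [toy_decoder()].
#' @return List with `image` (an `image_stimulus`: `height x width x 1`
#'   array in [0, 1]) and `features` (the embedding).
#' @export
toy_generator_and_features <- function(embedding, decoder) {
  if (length(embedding) != decoder$embed_dim) {
    stop_arg("embedding length ", length(embedding), " does not match decoder (",
             decoder$embed_dim, ")")
  }
  px <- 1 / (1 + exp(-drop(embedding %*% decoder$W)))
  img <- structure(
    list(pixels = array(px, c(decoder$height, decoder$width, 1L)),
         image_id = NA_integer_),
    class = "image_stimulus"
  )
  list(image = img, features = as.numeric(embedding))
}

#' @export
print.image_stimulus <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Image stimulus: %d x %d x %d, range [%.2f, %.2f]\n",
              d[1], d[2], d[3], min(x$pixels), max(x$pixels)))
  invisible(x)
}
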