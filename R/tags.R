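# Tag cards: the 5-slot semantic annotation scheme used by the CAT metric
# (2 broad-category tags, 1 specific, 1 background, 1 attribute per image).

#' Built-in hierarchical tag vocabulary
#'
#' A small fixture vocabulary: each semantic cluster of the concept bank owns
#' a pair of broad tags, and the specific / background / attribute slots draw
#' from shared pools. Cluster mates therefore share broad tags, which is what
#' makes partial CAT credit possible on synthetic data.
#'
#' @return List with elements `broad_1`, `broad_2` (one per cluster, recycled),
#'   `specific`, `background`, `attribute`.
#' @export
default_tag_vocabulary <- function() {
  list(
    broad_1 = c("animal", "vehicle", "food", "plant", "tool", "furniture",
                "clothing", "instrument"),
    broad_2 = c("mammal", "machine", "produce", "flora", "hardware",
                "household", "fabric", "acoustic"),
    specific = c("cat", "truck", "apple", "fern", "hammer", "chair", "scarf",
                 "guitar", "dog", "boat", "bread", "cactus", "wrench", "desk",
                 "jacket", "drum", "horse", "train", "cheese", "moss"),
    background = c("indoor", "outdoor", "studio", "field", "water", "sky"),
    attribute = c("furry", "metallic", "red", "green", "small", "large",
                  "round", "striped")
  )
}

validate_tag_vocabulary <- function(vocab) {
  slots <- c("broad_1", "broad_2", "specific", "background", "attribute")
  for (s in slots) {
    v <- vocab[[s]]
    if (is.null(v) || length(v) < 2L || any(!nzchar(v))) {
      stop_arg("tag vocabulary slot '", s, "' needs >= 2 non-empty entries")
    }
  }
  invisible(vocab)
}

normalize_tag <- function(x) tolower(trimws(x))

#' Generate tag cards for the test images of a bank
#'
#' One card per test image: broad tags are shared by all concepts in the same
#' cluster, the specific tag is tied to the category, and background /
#' attribute are drawn per image from the vocabulary pools.
#'
#' @param bank Concept bank.
#' @param vocab Tag vocabulary (see [default_tag_vocabulary()]).
#' @param seed Integer seed for the background/attribute draws.
#' @param layout Optional dataset layout (from [dataset_layout()]); defaults
#'   to one image per test category with image ids following the train block.
#' @return `data.frame` of class `tag_cards` with columns `image_id`,
#'   `broad_1`, `broad_2`, `specific`, `background`, `attribute` - exactly
#'   5 tags per image, all normalized lowercase.
#' @examples
#' bank <- make_concept_bank(20, 8, 5, seed = 1)
#' make_tag_cards(bank, seed = 1)
#' @export
make_tag_cards <- function(bank, vocab = default_tag_vocabulary(), seed = 1,
                           layout = dataset_layout(bank, 1)) {
  validate_tag_vocabulary(vocab)
  meta <- layout[layout$split == "test", , drop = FALSE]
  n <- nrow(meta)
  cl <- bank$cluster[meta$category_id]
  b1 <- vocab$broad_1[(cl - 1L) %% length(vocab$broad_1) + 1L]
  b2 <- vocab$broad_2[(cl - 1L) %% length(vocab$broad_2) + 1L]
  sp <- vocab$specific[(meta$category_id - 1L) %% length(vocab$specific) + 1L]
  with_seed(seed, {
    bg <- sample(vocab$background, n, replace = TRUE)
    at <- sample(vocab$attribute, n, replace = TRUE)
  })
  cards <- data.frame(
    image_id = meta$image_id,
    broad_1 = normalize_tag(b1), broad_2 = normalize_tag(b2),
    specific = normalize_tag(sp), background = normalize_tag(bg),
    attribute = normalize_tag(at),
    stringsAsFactors = FALSE
  )
  rownames(cards) <- NULL
  class(cards) <- c("tag_cards", "data.frame")
  cards
}

validate_tag_card <- function(card) {
  slots <- c("broad_1", "broad_2", "specific", "background", "attribute")
  vals <- unlist(card[slots], use.names = FALSE)
  if (length(vals) != 5L || anyNA(vals) || any(!nzchar(vals))) {
    stop_arg("malformed tag card: need exactly 5 non-empty tags")
  }
  invisible(card)
}

#' Write / read tag cards as CSV
#'
#' @param cards A `tag_cards` data frame.
#' @param path File path.
#' @return `read_tag_cards` returns the `tag_cards` data frame.
#' @export
write_tag_cards <- function(cards, path) {
  utils::write.csv(as.data.frame(cards), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_cards
#' @export
read_tag_cards <- function(path) {
  cards <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(cards) <- c("tag_cards", "data.frame")
  cards
}
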