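# Participant-dependent n-way zero-shot retrieval.
#
# Each test EEG embedding is matched against n candidate image embeddings
# (the true one plus n-1 distractors from other unseen categories) by cosine
# similarity; a prediction is correct when the ground truth ranks highest.
# Ties count against the model.

#' Rank of the true image among candidates
#'
#' 1-based rank of `candidate_embs[true_index, ]` when candidates are sorted
#' by descending cosine similarity to `eeg_emb`. A distractor tying the truth
#' is ranked above it (conservative reading of "ranked highest").
#'
#' @param eeg_emb Numeric query vector.
#' @param candidate_embs Matrix of candidate embeddings (rows).
#' @param true_index Row of the ground-truth candidate.
#' @return Integer rank in `1..nrow(candidate_embs)`.
#' @examples
#' rank_of_truth(c(1, 0), rbind(c(1, 0), c(0, 1)), 1)
#' @export
rank_of_truth <- function(eeg_emb, candidate_embs, true_index) {
  candidate_embs <- as.matrix(candidate_embs)
  if (true_index < 1 || true_index > nrow(candidate_embs)) {
    stop_arg("true_index out of range")
  }
  q <- eeg_emb / sqrt(sum(eeg_emb^2))
  cn <- unit_rows(candidate_embs)
  sims <- drop(cn %*% q)
  1L + sum(sims[-true_index] >= sims[true_index])
}

#' n-way zero-shot retrieval evaluation
#'
#' Samples `n_trials` (query, distractor-panel) pairs: a query EEG embedding
#' is drawn uniformly, its distractors are sampled without replacement from
#' images of other categories, and the rank of the truth is recorded. When
#' `n_way` equals the number of candidate images the single deterministic
#' full panel is used (one trial per query, no sampling).
#'
#' @param eeg_embs Matrix of test EEG embeddings (rows).
#' @param image_embs Matrix of candidate image embeddings (rows).
#' @param labels Integer vector: for each EEG row, the row of its true image
#'   in `image_embs`.
#' @param n_way Candidates per trial (2, 4, 10, 50, 100, 200 are the usual
#'   presets).
#' @param top_k Count a trial correct when the truth ranks within `top_k`.
#' @param n_trials Sampled trials (ignored for the full panel).
#' @param seed Integer seed for panel sampling.
#' @return Object of class `retrieval_report`: `n_way`, `top_k`, `n_trials`,
#'   `accuracy`, `per_trial_ranks`.
#' @export
evaluate_nway <- function(eeg_embs, image_embs, labels, n_way = 2,
                          top_k = 1, n_trials = 1000, seed = 1) {
  eeg_embs <- as.matrix(eeg_embs)
  image_embs <- as.matrix(image_embs)
  n_img <- nrow(image_embs)
  if (length(labels) != nrow(eeg_embs)) {
    stop_arg("labels must have one entry per EEG embedding")
  }
  if (n_way < 2 || n_way > n_img) {
    stop_arg("n_way must be between 2 and the number of candidate images (",
             n_img, ")")
  }
  if (top_k < 1 || top_k > n_way) stop_arg("need 1 <= top_k <= n_way")
  qn <- unit_rows(eeg_embs)
  cn <- unit_rows(image_embs)
  sims_all <- qn %*% t(cn) # full query x candidate cosine table

  ranks <- with_seed(seed, {
    if (n_way == n_img) {
      vapply(seq_len(nrow(qn)), function(i) {
        s <- sims_all[i, ]
        1L + sum(s[-labels[i]] >= s[labels[i]])
      }, integer(1))
    } else {
      vapply(seq_len(n_trials), function(tr) {
        i <- sample.int(nrow(qn), 1L)
        truth <- labels[i]
        pool <- which(seq_len(n_img) != truth)
        panel <- sample(pool, n_way - 1L)
        s <- sims_all[i, ]
        1L + sum(s[panel] >= s[truth])
      }, integer(1))
    }
  })

  structure(
    list(n_way = as.integer(n_way), top_k = as.integer(top_k),
         n_trials = length(ranks), accuracy = mean(ranks <= top_k),
         per_trial_ranks = ranks),
    class = "retrieval_report"
  )
}

#' @export
print.retrieval_report <- function(x, ...) {
  cat(sprintf("%d-way retrieval: top-%d accuracy %.3f over %d trials\n",
              x$n_way, x$top_k, x$accuracy, x$n_trials))
  invisible(x)
}

#' Retrieval over the standard n-way presets
#'
#' Evaluates a fitted contrastive model on the test split of a dataset for a
#' grid of `n_way` panels (clipped at the number of test images) and top-1 /
#' top-5 on the full panel, one row per setting.
#'
#' @param fit A `contrastive_fit`.
#' @param dataset A `synthetic_dataset`.
#' @param n_ways Panel sizes to evaluate.
#' @param n_trials Sampled trials per panel size.
#' @param seed Integer seed.
#' @return `data.frame` with columns `n_way`, `top_k`, `accuracy`, `n_trials`.
#' @export
retrieval_presets <- function(fit, dataset, n_ways = c(2, 4, 10, 50, 100, 200),
                              n_trials = 1000, seed = 1) {
  sh <- shared_embeddings(fit, dataset, "test")
  labels <- match(sh$meta$image_id, sh$img_meta$image_id)
  n_img <- nrow(sh$img)
  n_ways <- unique(pmin(n_ways, n_img))
  rows <- lapply(n_ways, function(nw) {
    rep_ <- evaluate_nway(sh$eeg, sh$img, labels, n_way = nw,
                          n_trials = n_trials, seed = derive_seed(seed, nw))
    data.frame(n_way = nw, top_k = 1L, accuracy = rep_$accuracy,
               n_trials = rep_$n_trials)
  })
  full <- evaluate_nway(sh$eeg, sh$img, labels, n_way = n_img,
                        top_k = min(5L, n_img), seed = seed)
  rows <- c(rows, list(data.frame(n_way = n_img, top_k = full$top_k,
                                  accuracy = full$accuracy,
                                  n_trials = full$n_trials)))
  do.call(rbind, rows)
}
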