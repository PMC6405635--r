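#' Build a nearest-centroid cosine-voting predictor
#'
#' For each signature (voter), the expression profiles of the training
#' samples are reduced to the signature's gene vector, and the arithmetic
#' mean vector (centroid) is computed separately for the RD (nonresponder)
#' and CR (responder) class. Prediction compares cosine distances to the
#' two centroids. Centroids should be computed on batch-normalized data;
#' the predictor stores the gene order of each voter so incoming samples
#' are projected identically.
#'
#' @param ds A normalized [expression_dataset()] containing both classes
#'   and all signature genes.
#' @param signatures An `mss_signature` tibble (each `category`/`list_id`
#'   pair becomes one voter), a named list of gene-id vectors, or a single
#'   character vector of gene ids.
#' @return An object of class `mss_predictor`.
#' @export
build_predictor <- function(ds, signatures) {
  stopifnot(inherits(ds, "expression_dataset"))
  voters <- as_voter_list(signatures)
  info <- sample_info(ds)
  rd_cols <- which(info$response == "RD")
  cr_cols <- which(info$response == "CR")
  if (length(rd_cols) == 0 || length(cr_cols) == 0) {
    abort("Training data must contain both RD and CR samples.")
  }
  values <- expr_values(ds)
  missing <- setdiff(unique(unlist(voters)), rownames(values))
  if (length(missing) > 0) {
    abort(paste0("Signature gene(s) absent from the training data: ",
                 cat_label(missing)))
  }
  fitted <- lapply(voters, function(genes) {
    x <- values[genes, , drop = FALSE]
    list(genes = genes,
         rd_centroid = rowMeans(x[, rd_cols, drop = FALSE]),
         cr_centroid = rowMeans(x[, cr_cols, drop = FALSE]))
  })
  structure(list(voters = fitted,
                 config = list(n_voters = length(fitted),
                               n_train = ncol(values),
                               n_rd = length(rd_cols),
                               n_cr = length(cr_cols))),
            class = "mss_predictor")
}

as_voter_list <- function(signatures) {
  if (is.character(signatures)) {
    return(list(signature = signatures))
  }
  if (is.list(signatures) && !is.data.frame(signatures)) {
    if (is.null(names(signatures))) {
      names(signatures) <- paste0("signature_", seq_along(signatures))
    }
    return(lapply(signatures, as.character))
  }
  tab <- as_tibble(signatures)
  if (!all(c("category", "gene_id") %in% names(tab))) {
    abort("`signatures` needs columns category and gene_id.")
  }
  if (!"list_id" %in% names(tab)) tab$list_id <- 1L
  keys <- distinct(tab[, c("category", "list_id")])
  multi <- any(tapply(keys$list_id, keys$category, length) > 1)
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sort(unique(tab$gene_id[tab$category == keys$category[i] &
                              tab$list_id == keys$list_id[i]]))
  })
  names(out) <- if (multi) {
    paste0(keys$category, "#", keys$list_id)
  } else {
    keys$category
  }
  out
}

#' Cosine-distance class vote for one sample
#'
#' Votes RD when the cosine distance (1 minus cosine similarity) from the
#' sample vector to the RD centroid is strictly smaller than to the CR
#' centroid, CR otherwise (exact ties vote CR with margin 0). The fuzzy
#' margin is `dist_CR - dist_RD`, positive when the sample leans RD. If any
#' vector has zero norm the cosine is undefined and the comparison falls
#' back to Euclidean distances.
#'
#' @param x Numeric sample vector (signature genes, training gene order).
#' @param rd_centroid,cr_centroid Class centroids of the same length.
#' @return List with elements `vote` (`"RD"` or `"CR"`) and `margin`.
#' @export
vote <- function(x, rd_centroid, cr_centroid) {
  stopifnot(length(x) == length(rd_centroid),
            length(x) == length(cr_centroid))
  nx <- sqrt(sum(x^2))
  nr <- sqrt(sum(rd_centroid^2))
  nc <- sqrt(sum(cr_centroid^2))
  if (nx == 0 || nr == 0 || nc == 0) {
    d_rd <- sqrt(sum((x - rd_centroid)^2))
    d_cr <- sqrt(sum((x - cr_centroid)^2))
  } else {
    d_rd <- 1 - sum(x * rd_centroid) / (nx * nr)
    d_cr <- 1 - sum(x * cr_centroid) / (nx * nc)
  }
  list(vote = if (d_rd < d_cr) "RD" else "CR", margin = d_cr - d_rd)
}

#' Predict response labels by signature voting
#'
#' Each voter casts a binary RD/CR vote per sample ([vote()]); the final
#' label is the majority. A tied vote is resolved by the sign of the summed
#' fuzzy margins (positive = RD) and flagged in `tie_broken`. With
#' `fuzzy = TRUE` the label is the sign of the summed margins directly.
#'
#' @param object An `mss_predictor`.
#' @param newdata An [expression_dataset()] or a genes-by-samples matrix
#'   containing all signature genes.
#' @param fuzzy Use fuzzy (summed-margin) voting instead of binary votes.
#' @param ... Unused.
#' @return An `mss_prediction` tibble: `sample_id`, `rd_votes`, `cr_votes`,
#'   `margin_sum`, `label`, `tie_broken`, and a `votes` list-column with
#'   the per-voter votes and margins.
#' @export
predict.mss_predictor <- function(object, newdata, fuzzy = FALSE, ...) {
  values <- if (inherits(newdata, "expression_dataset")) {
    expr_values(newdata)
  } else {
    newdata
  }
  if (is.null(dim(values))) values <- matrix(values, ncol = 1,
                                             dimnames = list(names(values),
                                                             "sample"))
  missing <- setdiff(unique(unlist(lapply(object$voters, `[[`, "genes"))),
                     rownames(values))
  if (length(missing) > 0) {
    abort(paste0("Gene(s) absent from `newdata`: ", cat_label(missing)))
  }
  samples <- colnames(values)
  per_sample <- lapply(seq_along(samples), function(j) {
    det <- lapply(names(object$voters), function(vn) {
      v <- object$voters[[vn]]
      res <- vote(values[v$genes, j], v$rd_centroid, v$cr_centroid)
      tibble(voter = vn, vote = res$vote, margin = res$margin)
    })
    bind_rows(det)
  })
  rd_votes <- vapply(per_sample, function(d) sum(d$vote == "RD"), 0L)
  cr_votes <- vapply(per_sample, function(d) sum(d$vote == "CR"), 0L)
  margin_sum <- vapply(per_sample, function(d) sum(d$margin), 0)
  if (isTRUE(fuzzy)) {
    label <- ifelse(margin_sum > 0, "RD", "CR")
    tie_broken <- rep(FALSE, length(samples))
  } else {
    tie <- rd_votes == cr_votes
    label <- ifelse(rd_votes > cr_votes, "RD",
                    ifelse(cr_votes > rd_votes, "CR",
                           ifelse(margin_sum > 0, "RD", "CR")))
    tie_broken <- tie
  }
  structure(tibble(sample_id = samples, rd_votes = rd_votes,
                   cr_votes = cr_votes, margin_sum = margin_sum,
                   label = label, tie_broken = tie_broken,
                   votes = per_sample),
            class = c("mss_prediction", class(tibble())),
            fuzzy = isTRUE(fuzzy))
}

#' @export
print.mss_predictor <- function(x, ...) {
  cat("<mss_predictor> ", length(x$voters), " voter(s): ",
      cat_label(names(x$voters)), "\n", sep = "")
  cat("  trained on ", x$config$n_train, " samples (",
      x$config$n_rd, " RD / ", x$config$n_cr, " CR)\n", sep = "")
  invisible(x)
}

#' @export
tidy.mss_predictor <- function(x, ...) {
  bind_rows(lapply(names(x$voters), function(vn) {
    v <- x$voters[[vn]]
    tibble(voter = vn, gene_id = v$genes,
           rd_centroid = unname(v$rd_centroid),
           cr_centroid = unname(v$cr_centroid))
  }))
}

#' @export
glance.mss_predictor <- function(x, ...) {
  tibble(n_voters = x$config$n_voters, n_train = x$config$n_train,
         n_rd = x$config$n_rd, n_cr = x$config$n_cr)
}

#' Serialize a predictor to JSON
#'
#' @param predictor An `mss_predictor`.
#' @param path Output file.
#' @export
write_predictor <- function(predictor, path) {
  payload <- list(
    config = predictor$config,
    voters = lapply(predictor$voters, function(v) {
      list(genes = v$genes, rd_centroid = unname(v$rd_centroid),
           cr_centroid = unname(v$cr_centroid))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_predictor
#' @export
read_predictor <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  voters <- lapply(payload$voters, function(v) {
    list(genes = as.character(v$genes),
         rd_centroid = setNames(as.numeric(v$rd_centroid),
                                as.character(v$genes)),
         cr_centroid = setNames(as.numeric(v$cr_centroid),
                                as.character(v$genes)))
  })
  structure(list(voters = voters, config = payload$config),
            class = "mss_predictor")
}
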