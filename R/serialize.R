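# Versioned JSON serialization for all model families. Trees are stored as
# explicit node tables (no opaque R objects), so models restored from JSON
# predict identically without the fitting packages' internals.

MODEL_FORMAT_VERSION <- 1L

#' Write a model to versioned JSON
#'
#' Supports PWM models, maximum-entropy models, boosting ensembles and
#' random forests. Forest trees are exported with
#' `randomForest::getTree()`; restored forests predict with the package's
#' own tree walker and give identical vote fractions.
#'
#' @param model A supported model object.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- if (inherits(model, "pwm_model")) {
    list(type = "pwm", site_kind = model$site_kind, length = model$length,
         freq = model$freq, pseudocount = model$pseudocount,
         min_logsum = model$min_logsum, max_logsum = model$max_logsum)
  } else if (inherits(model, "maxent_model")) {
    list(type = "maxent", site_kind = model$site_kind, length = model$length,
         constraint_order = model$constraint_order, k = model$k,
         grams = lapply(model$grams, as.vector),
         pseudocount = model$pseudocount, background = model$background,
         pos_freq = model$pos_freq, n_train = model$n_train, tol = model$tol)
  } else if (inherits(model, "scsnv_boost")) {
    list(type = "adaboost", variant = model$variant, loss = model$loss,
         n_iter = model$n_iter, shrinkage = model$shrinkage,
         maxdepth = model$maxdepth, trees = model$trees,
         scales = model$scales, features = model$features,
         loss_path = model$loss_path, seed = model$seed,
         n_train = model$n_train, class_counts = as.list(model$class_counts))
  } else if (inherits(model, "scsnv_forest")) {
    trees <- lapply(seq_len(model$n_trees), function(k) {
      m <- randomForest::getTree(model$fit, k, labelVar = FALSE)
      list(left = m[, "left daughter"], right = m[, "right daughter"],
           var = m[, "split var"], point = m[, "split point"],
           status = m[, "status"], pred = m[, "prediction"])
    })
    list(type = "random_forest", n_trees = model$n_trees, mtry = model$mtry,
         features = model$features, seed = model$seed,
         n_dropped = model$n_dropped, oob_error = model$oob_error,
         class_counts = as.list(model$class_counts), trees = trees)
  } else {
    stop("unsupported model class: ", paste(class(model), collapse = "/"),
         call. = FALSE)
  }
  payload$format_version <- MODEL_FORMAT_VERSION
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON file.
#' @return The restored model object. Restored forests carry explicit tree
#'   tables instead of a live `randomForest` fit.
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$format_version) || x$format_version > MODEL_FORMAT_VERSION)
    stop("unsupported model format version", call. = FALSE)
  if (x$type == "pwm") {
    freq <- matrix(unlist(x$freq), ncol = 4L, byrow = FALSE,
                   dimnames = list(NULL, DNA_BASES))
    if (is.matrix(x$freq)) freq <- x$freq
    colnames(freq) <- DNA_BASES
    structure(list(site_kind = x$site_kind, length = x$length, freq = freq,
                   pseudocount = x$pseudocount, min_logsum = x$min_logsum,
                   max_logsum = x$max_logsum), class = "pwm_model")
  } else if (x$type == "maxent") {
    k <- x$k
    # equal-length gram vectors may come back simplified into one matrix
    gl <- if (is.matrix(x$grams))
      lapply(seq_len(nrow(x$grams)), function(i) x$grams[i, ])
    else x$grams
    grams <- lapply(gl, function(g) array(unlist(g), dim = rep(4L, k)))
    pos_freq <- x$pos_freq
    structure(list(site_kind = x$site_kind, length = x$length,
                   constraint_order = x$constraint_order, k = k,
                   grams = grams, pseudocount = x$pseudocount,
                   background = x$background, pos_freq = pos_freq,
                   n_train = x$n_train, tol = x$tol),
              class = "maxent_model")
  } else if (x$type == "adaboost") {
    trees <- lapply(x$trees, function(tr) {
      tr <- as.data.frame(tr, stringsAsFactors = FALSE)
      tr$var <- as.character(tr$var)
      tr
    })
    structure(list(kind = "adaboost", variant = x$variant, loss = x$loss,
                   n_iter = x$n_iter, shrinkage = x$shrinkage,
                   maxdepth = x$maxdepth, trees = trees, scales = x$scales,
                   features = x$features, loss_path = x$loss_path,
                   seed = x$seed, n_train = x$n_train,
                   class_counts = unlist(x$class_counts)),
              class = c("scsnv_boost", "scsnv_ensemble"))
  } else if (x$type == "random_forest") {
    # jsonlite may simplify the tree list into a data frame of list columns
    trees <- if (is.data.frame(x$trees)) {
      lapply(seq_len(nrow(x$trees)), function(i)
        lapply(x$trees, function(col) unlist(col[[i]])))
    } else {
      x$trees
    }
    trees <- lapply(trees, as.data.frame)
    structure(list(kind = "random_forest", fit = NULL, trees = trees,
                   features = x$features, n_trees = x$n_trees,
                   mtry = x$mtry, n_dropped = x$n_dropped, seed = x$seed,
                   oob_error = x$oob_error,
                   class_counts = unlist(x$class_counts)),
              class = c("scsnv_forest", "scsnv_ensemble"))
  } else {
    stop("unknown model type: ", x$type, call. = FALSE)
  }
}

# vote fraction walker for forests restored from JSON; reproduces
# randomForest's new-data vote fractions (splits send x <= point left)
#' @noRd
forest_votes_restored <- function(model, X) {
  n <- nrow(X)
  votes <- numeric(n)
  Xm <- as.matrix(X[model$features])
  for (tr in model$trees) {
    node <- rep(1L, n)
    repeat {
      active <- which(tr$status[node] != -1L)
      if (!length(active)) break
      xv <- Xm[cbind(active, tr$var[node[active]])]
      left <- xv <= tr$point[node[active]]
      node[active] <- ifelse(left, tr$left[node[active]],
                             tr$right[node[active]])
    }
    votes <- votes + (tr$pred[node] == 2L)  # class "1" is level 2
  }
  votes / length(model$trees)
}
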