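#' Serialize fitted models to JSON
#'
#' Trees, bagging ensembles and rule sets round-trip through a JSON document
#' with full IEEE double precision, so a reloaded model reproduces every
#' prediction bit for bit.
#'
#' @param model A `vss_tree`, `vss_ensemble` or `rule_set`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  doc <- model_to_doc(model)
  json <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = FALSE)
  doc_to_model(doc)
}

model_to_doc <- function(model) {
  if (inherits(model, "vss_tree")) {
    list(model_class = "vss_tree",
         kind = model$kind,
         params = unclass(model$params),
         target = model$target,
         features = as.list(model$features),
         column_means = as.list(model$column_means),
         n_train = model$n_train,
         root_sd = model$root_sd,
         y_range = model$y_range,
         root = node_to_doc(model$root))
  } else if (inherits(model, "vss_ensemble")) {
    list(model_class = "vss_ensemble",
         n_trees = model$n_trees, seed = model$seed,
         params = unclass(model$params), target = model$target,
         members = lapply(model$members, model_to_doc))
  } else if (inherits(model, "rule_set")) {
    list(model_class = "rule_set",
         mode = model$mode,
         default_prediction = model$default_prediction,
         rules = lapply(model$rules, function(r) {
           list(conditions = lapply(seq_len(nrow(r$conditions)), function(i) {
             as.list(r$conditions[i, ])
           }),
           prediction_log = r$prediction_log,
           coverage = r$coverage)
         }))
  } else {
    abort("Unsupported model class for serialization.")
  }
}

node_to_doc <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", prediction = node$prediction, n_train = node$n_train,
         model = if (is.null(node$model)) NULL else
           list(intercept = node$model$intercept,
                coefficients = node$model$coefficients))
  } else {
    list(type = "split", descriptor = node$descriptor,
         threshold = node$threshold, n_train = node$n_train, mean = node$mean,
         left = node_to_doc(node$left), right = node_to_doc(node$right))
  }
}

doc_to_model <- function(doc) {
  switch(doc$model_class,
    vss_tree = {
      params <- doc$params
      params$tree_kind <- as.character(params$tree_kind)
      class(params) <- "tree_params"
      structure(list(root = doc_to_node(doc$root),
                     kind = doc$kind, params = params, target = doc$target,
                     features = as.character(unlist(doc$features)),
                     column_means = unlist(doc$column_means),
                     n_train = doc$n_train, root_sd = doc$root_sd,
                     y_range = if (is.null(doc$y_range)) NULL else
                       unlist(doc$y_range)),
                class = "vss_tree")
    },
    vss_ensemble = {
      params <- doc$params
      class(params) <- "tree_params"
      structure(list(members = lapply(doc$members, doc_to_model),
                     n_trees = doc$n_trees, seed = doc$seed, params = params,
                     target = doc$target),
                class = "vss_ensemble")
    },
    rule_set = {
      rules <- lapply(doc$rules, function(r) {
        conds <- dplyr::bind_rows(lapply(r$conditions, tibble::as_tibble))
        if (!nrow(conds)) conds <- empty_conditions()
        list(conditions = conds,
             prediction_log = r$prediction_log,
             coverage = r$coverage %||% NA_integer_)
      })
      new_rule_set(rules, doc$mode, doc$default_prediction)
    },
    abort("Unknown serialized model class.")
  )
}

doc_to_node <- function(doc) {
  if (doc$type == "leaf") {
    list(type = "leaf", prediction = doc$prediction, n_train = doc$n_train,
         model = if (is.null(doc$model)) NULL else
           list(intercept = doc$model$intercept,
                coefficients = doc$model$coefficients))
  } else {
    list(type = "split", descriptor = doc$descriptor,
         threshold = doc$threshold, n_train = doc$n_train, mean = doc$mean,
         left = doc_to_node(doc$left), right = doc_to_node(doc$right))
  }
}
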