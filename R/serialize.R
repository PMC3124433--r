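#' Serialise a model to JSON
#'
#' Writes a [markov_model()] or a `zi_background` collection to a JSON file
#' so that models can be exchanged between the command-line subcommands.
#' Matrices are stored as nested arrays; classes are recorded and restored
#' by [read_model_json()].
#'
#' @param model A `markov_model` or `zi_background` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  payload <- list(saarbg_class = class(model)[1], data = unclass_deep(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    out <- lapply(x, unclass_deep)
    if (!is.null(names(x))) names(out) <- names(x)
    out
  } else if (is.matrix(x)) {
    list(.matrix = TRUE, dim = dim(x), dimnames = dimnames(x),
         values = as.vector(x))
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)        # jsonlite drops names of atomic vectors
  } else x
}

#' Read a model serialised by [write_model_json()]
#'
#' @param path JSON file path.
#' @return The restored model object.
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyMatrix = FALSE,
                                 simplifyDataFrame = FALSE)
  model <- restore_node(payload$data)
  cls <- payload$saarbg_class
  if (cls == "markov_model") {
    markov_model(model$order, unlist(model$alphabet), model$transitions,
                 unlist(model$context_dist),
                 tuple_counts = unlist(model$tuple_counts))
  } else if (cls == "zi_background") {
    models <- lapply(model, restore_zi)
    structure(models, class = "zi_background")
  } else {
    stop("unknown serialised class: ", cls, call. = FALSE)
  }
}

restore_node <- function(x) {
  if (is.list(x)) {
    if (isTRUE(x$.matrix)) {
      m <- matrix(unlist(x$values), nrow = unlist(x$dim)[1])
      return(m)
    }
    lapply(x, restore_node)
  } else x
}

restore_zi <- function(m) {
  stage1 <- lapply(m$stage1, function(s) {
    gate <- s$gate
    if (!is.null(gate)) {
      gate <- structure(list(coefficients = unlist(gate$coefficients),
                             prevalence = gate$prevalence),
                        class = "logistic_stage")
    }
    list(degenerate = s$degenerate, gate = gate,
         threshold = s$threshold, prevalence = s$prevalence)
  })
  s2 <- m$stage2
  stage2 <- if (!is.null(s2$rv)) {
    structure(list(rv = as_matrix_cols(s2$rv, 3L), weights = unlist(s2$weights),
                   bias = s2$bias, h = s2$h, gamma = s2$gamma,
                   sigma2 = s2$sigma2, alpha = unlist(s2$alpha),
                   center = unlist(s2$center), scale = unlist(s2$scale),
                   n_params = s2$n_params, converged = s2$converged,
                   iterations = s2$iterations),
              class = "rvm_stage")
  } else {
    structure(list(coefficients = unlist(s2$coefficients),
                   exponents = as_matrix_cols(s2$exponents, 3L),
                   degree = s2$degree, n_params = s2$n_params),
              class = "poly_stage")
  }
  meta <- m$meta
  if (!is.null(meta$smear)) meta$smear <- unlist(meta$smear)
  zi_model(m$residue, unlist(m$n_range), stage1, stage2, m$kind,
           meta = meta)
}

as_matrix_cols <- function(x, ncol) {
  v <- unlist(x)
  matrix(v, ncol = ncol)
}
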