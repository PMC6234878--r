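#' Serialize / deserialize model masks as JSON
#'
#' A mask is stored as its dimension, state names, list of zero-constrained
#' cells and list of tied cell groups, so model grids can be archived beside
#' their fit tables.
#'
#' @param model An `mk_model`.
#' @param path Optional file; if `NULL`, the JSON string is returned.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "mk_model"))
  mask <- model$mask
  off <- which(row(mask) != col(mask), arr.ind = TRUE)
  zero <- off[mask[off] == 0L, , drop = FALSE]
  ties <- lapply(seq_len(model$n_par), function(p) {
    cells <- which(mask == p, arr.ind = TRUE)
    apply(cells, 1, function(rc) list(from = model$states[rc[1]],
                                      to = model$states[rc[2]]))
  })
  obj <- list(id = model$id, k = model$k, states = model$states,
              zero_cells = apply(zero, 1, function(rc)
                list(from = model$states[rc[1]], to = model$states[rc[2]])),
              parameters = ties)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname model_to_json
#' @param json JSON string or file path produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  k <- obj$k
  states <- unlist(obj$states)
  mask <- matrix(0L, k, k)
  off <- row(mask) != col(mask)
  mask[off] <- -1L # provisional: free unless zeroed or tied
  for (z in obj$zero_cells) {
    mask[match(z$from, states), match(z$to, states)] <- 0L
  }
  p <- 0L
  for (grp in obj$parameters) {
    p <- p + 1L
    for (cell in grp) {
      mask[match(cell$from, states), match(cell$to, states)] <- p
    }
  }
  if (any(mask == -1L)) {
    abort("JSON mask leaves cells unassigned", class = "phyniche_validation_error")
  }
  mk_model(k, "custom", mask = mask, states = states, id = obj$id)
}

#' Export a list of fits as a TSV table
#'
#' @param fits List of `mk_fit` objects.
#' @param path Output TSV path.
#' @return The glance table, invisibly.
#' @export
write_fits_tsv <- function(fits, path) {
  tab <- purrr::map_dfr(fits, glance)
  readr::write_tsv(tab, path)
  invisible(tab)
}
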