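#' State spaces of the two niche characters
#'
#' The multi-state preferred-substrate (PS) character uses a fixed,
#' ordered five-state alphabet; the binary generalist/specialist (GS)
#' character uses two. State spaces are fixed rather than data-driven so
#' that rate matrices and diversification parameter vectors stay comparable
#' across datasets even when a state happens to be unobserved.
#'
#' @return A character vector of state names.
#' @export
ps_states <- function() c("rock", "soil", "bark", "wood", "lichen")

#' @rdname ps_states
#' @export
gs_states <- function() c("generalist", "specialist")

#' Construct validated character data
#'
#' Wraps a two-column table (`species`, `state`) with an explicit ordered
#' state space. Every species must map to a state in the state space.
#'
#' @param x A data frame with columns `species` and `state` (extra columns
#'   are kept as annotations).
#' @param states Ordered character vector of allowed states (length >= 2).
#' @param name Character name, e.g. `"PS"` or `"GS"`.
#' @return A tibble of class `character_data` with attributes `states` and
#'   `char_name`.
#' @export
character_data <- function(x, states, name = "trait") {
  x <- as_tibble(x)
  if (!all(c("species", "state") %in% names(x))) {
    abort("character data needs columns 'species' and 'state'",
          class = "phyniche_validation_error")
  }
  if (length(states) < 2L) {
    abort("a character needs a state space of at least 2 states",
          class = "phyniche_validation_error")
  }
  x$species <- as.character(x$species)
  x$state <- tolower(as.character(x$state))
  if (anyDuplicated(x$species)) {
    abort("duplicated species rows in character table",
          class = "phyniche_validation_error")
  }
  bad <- setdiff(unique(x$state), states)
  if (length(bad) > 0) {
    abort(paste0("unknown state(s) ", paste(bad, collapse = ", "),
                 "; allowed states: ", paste(states, collapse = ", ")),
          class = "phyniche_validation_error")
  }
  structure(x, states = states, char_name = name,
            class = c("character_data", class(x)))
}

#' @export
print.character_data <- function(x, ...) {
  cat("<character_data>", attr(x, "char_name"), "— states:",
      paste(attr(x, "states"), collapse = ", "), "\n")
  NextMethod()
}

char_states <- function(data, states = NULL) {
  states %||% attr(data, "states") %||% sort(unique(data$state))
}

# Tip-likelihood indicator matrix aligned to tree tip order.
tip_state_matrix <- function(tree, data, states) {
  idx <- match(tree$tip.label, data$species)
  if (anyNA(idx)) {
    abort(paste0("tips missing from character data: ",
                 paste(tree$tip.label[is.na(idx)], collapse = ", ")),
          class = "phyniche_validation_error")
  }
  st <- match(data$state[idx], states)
  if (anyNA(st)) {
    abort("tip state outside the declared state space",
          class = "phyniche_validation_error")
  }
  m <- matrix(0, nrow = length(idx), ncol = length(states))
  m[cbind(seq_along(idx), st)] <- 1
  m
}

#' Classify species as generalist or specialist from occurrence counts
#'
#' A species is a specialist when strictly more than `threshold` of its
#' global occurrences come from a single substrate (default 95% rule).
#' The preferred substrate is the argmax substrate; for generalists the modal
#' substrate is reported with ties flagged rather than broken.
#'
#' @param occurrences Data frame with a `species` column and one non-negative
#'   integer count column per substrate.
#' @param threshold Specialist proportion threshold, strictly between 0 and 1.
#' @return A tibble: `species`, `gs` (generalist/specialist), `preferred`
#'   (substrate), `share` (max-substrate proportion), `tie` (modal-substrate
#'   tie flag).
#' @examples
#' occ <- data.frame(species = c("s1", "s2"), rock = c(96, 50), soil = c(4, 50))
#' classify_gs(occ)
#' @export
classify_gs <- function(occurrences, threshold = 0.95) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort("threshold must lie strictly between 0 and 1",
          class = "phyniche_validation_error")
  }
  occurrences <- as_tibble(occurrences)
  if (!"species" %in% names(occurrences)) {
    abort("occurrence table needs a 'species' column",
          class = "phyniche_validation_error")
  }
  substrates <- setdiff(names(occurrences), "species")
  counts <- as.matrix(occurrences[substrates])
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("occurrence counts must be finite and non-negative",
          class = "phyniche_validation_error")
  }
  rs <- rowSums(counts)
  if (any(rs <= 0)) {
    abort(paste0("all-zero occurrence row(s): ",
                 paste(occurrences$species[rs <= 0], collapse = ", ")),
          class = "phyniche_validation_error")
  }
  share <- counts / rs
  top <- apply(share, 1, max)
  n_top <- rowSums(abs(share - top) < 1e-12)
  pref <- substrates[apply(share, 1, which.max)]
  tibble(
    species = occurrences$species,
    gs = ifelse(top > threshold, "specialist", "generalist"),
    preferred = pref,
    share = top,
    tie = n_top > 1L
  )
}

#' Sampling completeness fractions
#'
#' Per-group (state or clade) ratio of species included in the tree to
#' species known to science; used as sampling fractions in diversification
#' models.
#'
#' @param included Named non-negative integer vector (or column) of included
#'   species counts.
#' @param known Named positive integer vector of described species counts,
#'   same names.
#' @return A tibble: `group`, `included`, `known`, `fraction`.
#' @export
sampling_fractions <- function(included, known) {
  if (!identical(length(included), length(known))) {
    abort("included and known must have the same length",
          class = "phyniche_validation_error")
  }
  groups <- names(included) %||% names(known) %||% as.character(seq_along(included))
  if (any(known <= 0)) {
    abort("known species counts must be positive",
          class = "phyniche_validation_error")
  }
  if (any(included > known)) {
    abort("included cannot exceed known species counts",
          class = "phyniche_validation_error")
  }
  if (any(included <= 0)) {
    abort("groups with zero included species are unobservable",
          class = "phyniche_validation_error")
  }
  tibble(group = groups, included = as.numeric(included),
         known = as.numeric(known), fraction = included / known)
}

#' @rdname sampling_fractions
#' @param groups Character vector of group names for the complete-sampling
#'   scenario (every fraction 1).
#' @export
complete_sampling <- function(groups) {
  tibble(group = as.character(groups), included = NA_real_, known = NA_real_,
         fraction = 1)
}

#' Read / write a tip character table
#'
#' CSV/TSV with a header: columns `species`, `ps_state`, `gs_state` (state
#' names case-insensitive on input, canonical lowercase internally). Extra
#' columns (e.g. secondary-substrate annotations or occurrence counts) are
#' retained as annotations. If a tree is supplied, tips present on only one
#' side are reported via a message.
#'
#' @param path CSV or TSV file path (delimiter sniffed from the extension).
#' @param tree Optional `phylo` used to cross-check tip coverage.
#' @return A list with elements `ps` and `gs` (both `character_data`) and
#'   `annotations` (tibble of any extra columns).
#' @export
read_character_table <- function(path, tree = NULL) {
  if (!file.exists(path)) {
    abort(paste0("character table not found: ", path),
          class = "phyniche_io_error")
  }
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(tab) <- tolower(names(tab))
  if (!"species" %in% names(tab)) {
    abort("character table is missing the 'species' column",
          class = "phyniche_validation_error")
  }
  if (!all(c("ps_state", "gs_state") %in% names(tab))) {
    abort("character table needs 'ps_state' and 'gs_state' columns",
          class = "phyniche_validation_error")
  }
  if (!is.null(tree)) {
    only_table <- setdiff(tab$species, tree$tip.label)
    only_tree <- setdiff(tree$tip.label, tab$species)
    if (length(only_table) > 0) {
      message("species in table but not in tree: ",
              paste(only_table, collapse = ", "))
    }
    if (length(only_tree) > 0) {
      message("tips in tree but not in table: ",
              paste(only_tree, collapse = ", "))
    }
  }
  extra <- setdiff(names(tab), c("ps_state", "gs_state"))
  list(
    ps = character_data(
      tibble(species = tab$species, state = tab$ps_state),
      states = ps_states(), name = "PS"),
    gs = character_data(
      tibble(species = tab$species, state = tab$gs_state),
      states = gs_states(), name = "GS"),
    annotations = tab[extra]
  )
}

#' @rdname read_character_table
#' @param ps,gs `character_data` objects to serialize.
#' @export
write_character_table <- function(ps, gs, path) {
  stopifnot(identical(ps$species, gs$species))
  tab <- tibble(species = ps$species, ps_state = ps$state, gs_state = gs$state)
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(tab, path, delim = delim)
  invisible(path)
}
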