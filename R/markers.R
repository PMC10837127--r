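#' Construct a marker specification
#'
#' An ordered map from cell-type name to its positive (characteristically
#' over-expressed) markers and, optionally, negative markers whose absence
#' characterises the type. Type order is meaningful: it defines the
#' round-robin order of ranked initial selection and the tie-break when
#' clusters are assigned to types.
#'
#' @param positive Named list: type -> character vector of positive markers
#'   (each type needs at least one).
#' @param negative Optional named list of negative markers per type.
#' @return An object of class `marker_spec`.
#' @export
#' @examples
#' marker_spec(list(Tcell = c("CD3D", "CD3E"), Bcell = "MS4A1"))
marker_spec <- function(positive, negative = list()) {
  if (is.null(names(positive)) || any(names(positive) == "")) {
    abort("`positive` must be a named list (type -> markers)")
  }
  types <- names(positive)
  if (anyDuplicated(types)) abort("duplicate cell-type names in marker spec")
  positive <- lapply(positive, as.character)
  n_pos <- vapply(positive, length, integer(1))
  if (any(n_pos == 0)) {
    abort(sprintf("types without positive markers: %s",
                  paste(types[n_pos == 0], collapse = ", ")))
  }
  negative <- lapply(negative, as.character)
  neg <- setNames(vector("list", length(types)), types)
  for (t in types) neg[[t]] <- negative[[t]] %||% character(0)
  both <- vapply(types, function(t) length(intersect(positive[[t]], neg[[t]])) > 0,
                 logical(1))
  if (any(both)) {
    abort(sprintf("marker listed as both positive and negative for: %s",
                  paste(types[both], collapse = ", ")))
  }
  structure(list(types = types, positive = positive, negative = neg),
            class = "marker_spec")
}

#' @export
print.marker_spec <- function(x, ...) {
  cat(sprintf("<marker_spec> %d cell types\n", length(x$types)))
  for (t in x$types) {
    cat(sprintf("  %s: +%d markers%s\n", t, length(x$positive[[t]]),
                if (length(x$negative[[t]]))
                  sprintf(", -%d markers", length(x$negative[[t]])) else ""))
  }
  invisible(x)
}

#' Tidy a marker specification into a long table
#'
#' @param x A `marker_spec`.
#' @param ... Unused.
#' @return A tibble with columns `cell_type`, `marker`, `direction`.
#' @export
tidy.marker_spec <- function(x, ...) {
  rows <- purrr::map(x$types, function(t) {
    bind_rows(
      tibble(cell_type = t, marker = x$positive[[t]], direction = "positive"),
      if (length(x$negative[[t]]))
        tibble(cell_type = t, marker = x$negative[[t]], direction = "negative")
    )
  })
  bind_rows(rows)
}

#' All marker names in a spec
#' @param spec A `marker_spec`.
#' @return Character vector of unique marker names (both directions).
#' @export
marker_union <- function(spec) {
  unique(c(unlist(spec$positive, use.names = FALSE),
           unlist(spec$negative, use.names = FALSE)))
}

#' Read a marker table
#'
#' YAML layout: `type: {positive: [...], negative: [...]}` (a bare list
#' under a type is read as its positive markers). CSV layout: long table
#' with columns `cell_type, marker, direction` where direction is
#' `positive` or `negative`. Type order follows order of first appearance.
#'
#' @param path File to read.
#' @param format `"yaml"` or `"csv"` (default guessed from the extension).
#' @return A `marker_spec`.
#' @export
load_markers <- function(path, format = c("auto", "yaml", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.ya?ml$", path)) "yaml" else "csv"
  }
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "yaml") {
    raw <- yaml::read_yaml(path)
    if (!is.list(raw) || is.null(names(raw))) {
      abort(sprintf("%s: expected a mapping of cell types", path))
    }
    pos <- list(); neg <- list()
    for (t in names(raw)) {
      entry <- raw[[t]]
      if (is.list(entry) && !is.null(names(entry))) {
        pos[[t]] <- unlist(entry$positive) %||% character(0)
        if (!is.null(entry$negative)) neg[[t]] <- unlist(entry$negative)
      } else {
        pos[[t]] <- unlist(entry) %||% character(0)
      }
    }
    marker_spec(pos, neg)
  } else {
    df <- read.csv(path, check.names = FALSE)
    need <- c("cell_type", "marker", "direction")
    if (!all(need %in% names(df))) {
      abort(sprintf("%s: marker CSV needs columns %s", path,
                    paste(need, collapse = ", ")))
    }
    bad <- !df$direction %in% c("positive", "negative")
    if (any(bad)) {
      abort(sprintf("%s: invalid direction values at rows %s", path,
                    paste(which(bad), collapse = ", ")))
    }
    types <- unique(df$cell_type)
    pos <- lapply(setNames(types, types), function(t)
      df$marker[df$cell_type == t & df$direction == "positive"])
    neg <- lapply(setNames(types, types), function(t)
      df$marker[df$cell_type == t & df$direction == "negative"])
    marker_spec(pos, neg[vapply(neg, length, integer(1)) > 0])
  }
}

#' Write a marker table
#'
#' @param spec A `marker_spec`.
#' @param path Output file.
#' @param format `"yaml"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_markers <- function(spec, path, format = c("yaml", "csv")) {
  format <- match.arg(format)
  if (format == "yaml") {
    out <- lapply(setNames(spec$types, spec$types), function(t) {
      e <- list(positive = as.list(spec$positive[[t]]))
      if (length(spec$negative[[t]])) e$negative <- as.list(spec$negative[[t]])
      e
    })
    yaml::write_yaml(out, path)
  } else {
    write.csv(tidy.marker_spec(spec), path, row.names = FALSE)
  }
  invisible(path)
}
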