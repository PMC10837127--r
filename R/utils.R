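#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions never disturb the global stream.
#' A `NULL` seed evaluates the code as-is.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed from a base seed and a stream index,
# staying inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647L)
}

# Round half away from zero (round(0.5) in the "schoolbook" sense); base
# round() is banker's rounding, which the selection quotas must not use.
round_half_up <- function(x) floor(x + 0.5)

#' Largest-remainder apportionment with capacity-aware redistribution
#'
#' Splits `n` selections across pools of the given sizes as evenly as
#' possible. Pools smaller than their even share contribute everything they
#' have and the deficit is re-spread evenly over pools with spare capacity,
#' repeatedly, using largest-remainder rounding; ties go to the earliest
#' pool in the order given.
#'
#' @param sizes Integer vector of pool capacities.
#' @param n Total number of items to allocate; must not exceed `sum(sizes)`.
#' @return Integer vector of per-pool allocations summing to `n`.
#' @keywords internal
#' @noRd
distribute_quota <- function(sizes, n) {
  sizes <- as.integer(sizes)
  stopifnot(all(sizes >= 0), n >= 0)
  if (n > sum(sizes)) {
    abort(sprintf("requested %d items but pools hold only %d", n, sum(sizes)))
  }
  alloc <- integer(length(sizes))
  remaining <- n
  while (remaining > 0L) {
    spare <- sizes - alloc
    active <- which(spare > 0L)
    share <- remaining / length(active)
    base <- pmin(floor(share), spare[active])
    extras <- remaining - sum(base)
    frac <- share - floor(share)
    # one extra item per pool, ordered by fractional remainder (all equal
    # here since the share is common) then pool position
    add <- base
    if (extras > 0L) {
      can_take <- which(spare[active] > base)
      take <- head(can_take, extras)
      add[take] <- add[take] + 1L
      extras <- extras - length(take)
    }
    if (sum(add) == 0L) { # every active pool smaller than 1 share unit
      take <- head(active, remaining)
      alloc[take] <- alloc[take] + 1L
      remaining <- remaining - length(take)
      next
    }
    alloc[active] <- alloc[active] + add
    remaining <- n - sum(alloc)
  }
  alloc
}

# Coerce a labels input (two-column data frame cell_id/cell_type, or a
# named character vector) to the canonical tibble form.
as_label_frame <- function(labels, arg = "labels") {
  if (is.data.frame(labels)) {
    if (!all(c("cell_id", "cell_type") %in% names(labels))) {
      abort(sprintf("`%s` must have columns cell_id and cell_type", arg))
    }
    out <- tibble(cell_id = as.character(labels$cell_id),
                  cell_type = as.character(labels$cell_type))
  } else if (!is.null(names(labels))) {
    out <- tibble(cell_id = names(labels), cell_type = as.character(labels))
  } else {
    abort(sprintf("`%s` must be a data frame or a named character vector", arg))
  }
  if (anyDuplicated(out$cell_id)) {
    abort(sprintf("duplicate cell ids in `%s`", arg))
  }
  out
}

# Labels as a named character vector indexed by cell id.
label_lookup <- function(labels) {
  lf <- as_label_frame(labels)
  setNames(lf$cell_type, lf$cell_id)
}

reserved_label_tokens <- function() c("unassigned", "unknown")

assert_no_reserved <- function(labels, arg = "labels") {
  lf <- as_label_frame(labels, arg)
  bad <- lf$cell_type %in% reserved_label_tokens()
  if (any(bad)) {
    abort(sprintf(
      "`%s` contains reserved tokens (%s) for %d cells; ground-truth labels must name real types",
      arg, paste(unique(lf$cell_type[bad]), collapse = ", "), sum(bad)
    ))
  }
  invisible(lf)
}
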