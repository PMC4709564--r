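#' Domain maps: named residue-range selections
#'
#' A domain map names groups of residues (e.g. the MHC I heavy-chain domains
#' alpha1/alpha2/alpha3, beta-2 microglobulin, the antigen peptide Ag, and the
#' tapasin N- and C-terminal domains TN/TC) as sets of closed residue-index
#' intervals on author/PDB numbering, optionally restricted to a chain.
#' Selections drive the per-domain entropy decomposition and the force-analysis
#' group split.
#'
#' @param ... Named selections. Each is a data frame (or list coercible to
#'   one) with columns `chain_id` (string or `NA` for any chain), `from`,
#'   `to` (integer residue indices, closed interval).
#' @return An object of class `domain_map`: a named list of tibbles.
#' @export
#' @examples
#' dm <- domain_map(
#'   TN = data.frame(chain_id = "C", from = 1, to = 269),
#'   TC = data.frame(chain_id = "C", from = 270, to = 381))
#' names(dm)
domain_map <- function(...) {
  sels <- list(...)
  if (length(sels) == 1 && is.list(sels[[1]]) && is.null(names(sels)[1]) &&
      !is.data.frame(sels[[1]])) {
    sels <- sels[[1]]
  }
  if (is.null(names(sels)) || any(!nzchar(names(sels)))) {
    stop("every selection must be named")
  }
  if (anyDuplicated(names(sels))) stop("selection names must be unique")
  sels <- lapply(sels, function(s) {
    s <- tibble::as_tibble(s)
    if (!all(c("from", "to") %in% names(s))) {
      stop("each selection needs columns from, to")
    }
    if (!"chain_id" %in% names(s)) s$chain_id <- NA_character_
    s$chain_id <- as.character(s$chain_id)
    s$from <- as.integer(s$from)
    s$to <- as.integer(s$to)
    if (any(s$to < s$from)) stop("selection interval with to < from")
    s[, c("chain_id", "from", "to")]
  })
  structure(sels, class = "domain_map")
}

#' @export
print.domain_map <- function(x, ...) {
  cat("<domain_map> ", length(x), " selection(s)\n", sep = "")
  for (nm in names(x)) {
    s <- x[[nm]]
    iv <- paste0(ifelse(is.na(s$chain_id), "", paste0(s$chain_id, ":")),
                 s$from, "-", s$to, collapse = ", ")
    cat("  ", format(nm, width = 8), " ", iv, "\n", sep = "")
  }
  invisible(x)
}

#' Read or write a domain map as YAML
#'
#' The on-disk form is a YAML mapping from selection name to a list of
#' `{chain: "A", from: 1, to: 90}` entries (`chain` optional).
#'
#' @param path YAML file.
#' @return A [domain_map()].
#' @export
read_domain_map <- function(path) {
  y <- yaml::read_yaml(path)
  sels <- lapply(y, function(entries) {
    if (!is.null(names(entries)) && any(c("from", "to") %in% names(entries))) {
      entries <- list(entries)  # single interval not wrapped in a list
    }
    do.call(rbind, lapply(entries, function(e) {
      data.frame(chain_id = if (is.null(e$chain)) NA_character_ else as.character(e$chain),
                 from = as.integer(e$from), to = as.integer(e$to))
    }))
  })
  domain_map(sels)
}

#' @rdname read_domain_map
#' @param map A [domain_map()].
#' @export
write_domain_map <- function(map, path) {
  y <- lapply(unclass(map), function(s) {
    lapply(seq_len(nrow(s)), function(i) {
      e <- list(from = s$from[i], to = s$to[i])
      if (!is.na(s$chain_id[i])) e <- c(list(chain = s$chain_id[i]), e)
      e
    })
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Resolve a named selection to atom indices
#'
#' Maps a named selection of a [domain_map()] onto a topology, returning the
#' sorted indices (1-based positions in the topology's atom order) of the
#' matching atoms. The `CA` filter keeps exactly one alpha-carbon per
#' amino-acid residue (atom name "CA", element C); `heavy` drops hydrogens.
#'
#' @param map A [domain_map()].
#' @param name Selection name present in `map`.
#' @param topology A [topology()].
#' @param atom_filter One of `"all"`, `"CA"`, `"heavy"`.
#' @return Sorted integer vector of atom indices; errors if empty.
#' @export
resolve_selection <- function(map, name, topology,
                              atom_filter = c("all", "CA", "heavy")) {
  atom_filter <- match.arg(atom_filter)
  if (!name %in% names(map)) {
    stop("selection '", name, "' not in map (has: ",
         paste(names(map), collapse = ", "), ")")
  }
  a <- topology$atoms
  s <- map[[name]]
  hit <- rep(FALSE, nrow(a))
  for (i in seq_len(nrow(s))) {
    in_range <- a$residue_index >= s$from[i] & a$residue_index <= s$to[i]
    if (!is.na(s$chain_id[i])) in_range <- in_range & a$chain_id == s$chain_id[i]
    hit <- hit | in_range
  }
  hit <- hit & switch(atom_filter,
    all = TRUE,
    CA = a$name == "CA" & a$element == "C",
    heavy = a$element != "H"
  )
  idx <- which(hit)
  if (length(idx) == 0) {
    stop("selection '", name, "' resolves to zero atoms with filter '",
         atom_filter, "'")
  }
  sort(idx)
}

#' Default domain map for the tapasin-MHC I system
#'
#' Ships the conventional residue ranges: MHC I heavy chain alpha1 (1-90),
#' alpha2 (91-182), alpha3 (183-276) — the alpha1/alpha2/alpha3 boundaries are
#' approximate and user-overridable — beta-2 microglobulin, the antigen
#' peptide, and tapasin TN (1-269) / TC (270-381).
#'
#' @param chain_mhc,chain_b2m,chain_ag,chain_tapasin Chain identifiers for the
#'   four polypeptides.
#' @return A [domain_map()].
#' @export
default_domain_map <- function(chain_mhc = "A", chain_b2m = "B",
                               chain_ag = "C", chain_tapasin = "D") {
  domain_map(
    alpha1 = data.frame(chain_id = chain_mhc, from = 1, to = 90),
    alpha2 = data.frame(chain_id = chain_mhc, from = 91, to = 182),
    alpha3 = data.frame(chain_id = chain_mhc, from = 183, to = 276),
    b2m = data.frame(chain_id = chain_b2m, from = 1, to = 99),
    Ag = data.frame(chain_id = chain_ag, from = 1, to = 9),
    TN = data.frame(chain_id = chain_tapasin, from = 1, to = 269),
    TC = data.frame(chain_id = chain_tapasin, from = 270, to = 381)
  )
}
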