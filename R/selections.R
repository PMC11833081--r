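# Atom selections and residue-group config parsing.

#' Select atoms by chain and residue numbers
#'
#' Resolves a residue group (e.g. the occluding loop, residues 185-200 of
#' cathepsin B in UniProt numbering) to an ordered list of atom indices.
#'
#' @param topology Topology data frame of a `StructureEnsemble`.
#' @param chain Chain identifier (single character).
#' @param residue_numbers Integer vector of residue numbers; order and
#'   duplicates are irrelevant.
#' @param heavy_only Keep only non-hydrogen atoms (default `TRUE`).
#' @param label Optional selection label; defaults to a `chain:residues`
#'   description.
#' @return An `AtomSelection`: list with `atom_indices` (1-based, ascending,
#'   unique) and `label`.
#' @export
select_atoms <- function(topology, chain, residue_numbers, heavy_only = TRUE,
                         label = NULL) {
  if (length(residue_numbers) == 0L) stop("residue_numbers must be non-empty")
  residue_numbers <- unique(as.integer(residue_numbers))
  hit <- topology$chain_id == chain &
    topology$residue_number %in% residue_numbers
  if (heavy_only) hit <- hit & topology$is_heavy
  idx <- topology$atom_index[hit]
  if (length(idx) == 0L)
    stop("selection error: no atoms on chain '", chain, "' with residues {",
         paste(sort(residue_numbers), collapse = ","), "}")
  if (is.null(label))
    label <- paste0(chain, ":", paste(unique(range(sort(residue_numbers))), collapse = "-"))
  structure(list(atom_indices = sort(idx), label = label),
            class = "AtomSelection")
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat(sprintf("AtomSelection '%s': %d atoms\n", x$label, length(x$atom_indices)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse a residue specification string
#'
#' Accepts comma-separated residue numbers and inclusive ranges, e.g.
#' `"185-200"` or `"108,278,298"` or a mixture.
#'
#' @param spec Character scalar (or numeric vector, returned as-is).
#' @return Sorted integer vector of residue numbers.
#' @export
parse_residue_spec <- function(spec) {
  if (is.numeric(spec)) return(sort(unique(as.integer(spec))))
  parts <- trimws(strsplit(as.character(spec), ",", fixed = TRUE)[[1]])
  res <- unlist(lapply(parts, function(p) {
    if (grepl("^[0-9]+-[0-9]+$", p)) {
      bounds <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      seq(bounds[1], bounds[2])
    } else {
      as.integer(p)
    }
  }))
  if (anyNA(res)) stop("unparseable residue spec: ", spec)
  sort(unique(res))
}

#' Read residue-group definitions from a key-value config file
#'
#' Each group line has the form
#' `group.<name> = chain:<id> residues:<start-end,list> heavy_only:<bool>`
#' (whitespace-separated fields; `heavy_only` defaults to true). Blank lines
#' and lines starting with `#` are skipped.
#'
#' @param path Config file path.
#' @return Named list of group definitions, each a list with `chain`,
#'   `residue_numbers`, `heavy_only`.
#' @export
read_selection_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lines <- grep("^group\\.", lines, value = TRUE)
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed group line: ", ln)
    name <- sub("^group\\.", "", trimws(kv[1]))
    fields <- strsplit(trimws(kv[2]), "[[:space:]]+")[[1]]
    get_field <- function(key) {
      v <- grep(paste0("^", key, ":"), fields, value = TRUE)
      if (length(v) == 0L) return(NULL)
      sub(paste0("^", key, ":"), "", v[1])
    }
    chain <- get_field("chain")
    res <- get_field("residues")
    if (is.null(chain) || is.null(res))
      stop("group '", name, "' needs chain: and residues: fields")
    out[[name]] <- list(
      chain = chain,
      residue_numbers = parse_residue_spec(res),
      heavy_only = !identical(tolower(get_field("heavy_only") %||% "true"), "false")
    )
  }
  out
}

#' Built-in analysis preset for murine cathepsin B / cystatin C
#'
#' Residue groups and constants for the occluding-loop analysis of murine
#' cathepsin B (UniProt numbering): loop residues 185-200, active-site
#' residues 108, 278 and 298, the allosteric-pocket residue set used for
#' mutagenesis (169, 215, 221, 222, 224, 333), the 16.5 A closed-state
#' distance threshold and the 3.3 A heavy-atom contact cutoff.
#'
#' @param enzyme_chain Chain id carrying the enzyme (default "A").
#' @return Named list with `loop`, `active_site`, `pocket`,
#'   `threshold`, `cutoff`, `enzyme_chain`.
#' @export
preset_ctsb_murine <- function(enzyme_chain = "A") {
  list(
    loop = 185:200,
    active_site = c(108L, 278L, 298L),
    pocket = c(169L, 215L, 221L, 222L, 224L, 333L),
    threshold = 16.5,
    cutoff = 3.3,
    enzyme_chain = enzyme_chain
  )
}
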