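## SMILES handling on top of Open Babel (ChemmineOB). All canonicalization,
## validity checking and atom-order randomization go through here.

#' @importFrom ChemmineOB convertFormat
NULL

## Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Batch-convert SMILES through Open Babel. Returns a character vector aligned
## with `smiles`; entries that fail to parse come back NA. The `e` option makes
## Open Babel carry on past invalid entries instead of aborting the batch.
ob_convert <- function(smiles, to = "CAN") {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  inp <- paste(paste(smiles, seq_len(n)), collapse = "\n")
  out <- ChemmineOB::convertFormat("SMI", to, inp,
                                   options = data.frame(names = "e", args = ""))
  res <- rep(NA_character_, n)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      idx <- suppressWarnings(as.integer(parts[2]))
      if (!is.na(idx) && idx >= 1 && idx <= n) res[idx] <- parts[1]
    }
  }
  res
}

sort_components <- function(s) {
  vapply(strsplit(s, ".", fixed = TRUE), function(p) {
    paste(sort(p), collapse = ".")
  }, character(1))
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the toolkit-canonical rendering (Open Babel canonical
#' SMILES), preserving tetrahedral stereo annotations. Multi-molecule strings
#' (dot-separated) have their components sorted lexicographically after
#' canonicalization so that reagent order never distinguishes two otherwise
#' identical reactions. The operation is idempotent.
#'
#' @param s character vector of SMILES strings (non-empty).
#' @param strict if `TRUE` (default) an unparsable SMILES raises an error; if
#'   `FALSE` it yields `NA` in the output.
#' @return character vector of canonical SMILES, same length as `s`.
#' @export
canonicalize_smiles <- function(s, strict = TRUE) {
  stopifnot(is.character(s))
  if (any(!nzchar(s))) stop("canonicalize_smiles: empty SMILES string")
  out <- ob_convert(s, "CAN")
  if (strict && anyNA(out)) {
    bad <- s[is.na(out)]
    stop("canonicalize_smiles: failed to parse SMILES: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ok <- !is.na(out)
  out[ok] <- sort_components(out[ok])
  out
}

#' Test whether SMILES strings are valid
#'
#' @param s character vector of SMILES strings.
#' @return logical vector; `TRUE` where the string parses.
#' @export
smiles_valid <- function(s) {
  ok <- nzchar(s)
  ok[ok] <- !is.na(ob_convert(s[ok], "CAN"))
  ok
}

## Rooted SMILES rendering: rewrite each single-molecule SMILES starting from
## the given atom index (1-based, heavy atoms in input order). Batched through
## the obabel CLI, grouping inputs that share a root index into one call.
ob_rooted <- function(smiles, roots) {
  stopifnot(length(smiles) == length(roots))
  res <- rep(NA_character_, length(smiles))
  for (r in unique(roots)) {
    sel <- which(roots == r)
    inp <- tempfile(fileext = ".smi")
    writeLines(paste(smiles[sel], sel), inp)
    out <- suppressWarnings(
      system2("obabel", c(inp, "-osmi", "-e", "-xf", r),
              stdout = TRUE, stderr = FALSE))
    unlink(inp)
    for (ln in out) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(parts) >= 2) {
        idx <- suppressWarnings(as.integer(trimws(parts[2])))
        if (!is.na(idx)) res[idx] <- parts[1]
      }
    }
  }
  res
}

#' Generate a randomized (non-canonical) SMILES rendering
#'
#' Produces an atom-order permutation of the input molecule(s): each
#' dot-separated component is rewritten starting from a randomly chosen root
#' atom and the component order is shuffled. The result encodes the same
#' molecule (identical canonical form) and is deterministic for a fixed seed.
#'
#' @param s character vector of valid SMILES strings.
#' @param seed integer seed controlling root-atom and component-order choice.
#' @return character vector of randomized SMILES.
#' @export
randomize_smiles <- function(s, seed) {
  stopifnot(is.character(s), length(s) >= 1)
  comps <- strsplit(s, ".", fixed = TRUE)
  flat <- unlist(comps, use.names = FALSE)
  nat <- vapply(flat, n_heavy_atoms, integer(1), USE.NAMES = FALSE)
  if (any(nat < 1)) stop("randomize_smiles: untokenizable SMILES")
  roots <- with_seed(seed, vapply(nat, function(k) sample.int(k, 1), integer(1)))
  rnd <- ob_rooted(flat, roots)
  ## a root choice Open Babel refuses, or a rendering that does not
  ## round-trip to the same molecule (rare writer quirks with explicit
  ## hydrogen counts), falls back to the input rendering
  bad <- is.na(rnd)
  if (any(!bad)) {
    chk <- canonicalize_smiles(rnd[!bad], strict = FALSE)
    ref <- canonicalize_smiles(flat[!bad], strict = FALSE)
    bad[!bad] <- is.na(chk) | chk != ref
  }
  rnd[bad] <- flat[bad]
  idx <- rep(seq_along(s), lengths(comps))
  out <- character(length(s))
  with_seed(seed + 1L, {
    for (i in seq_along(s)) {
      parts <- rnd[idx == i]
      if (length(parts) > 1) parts <- parts[sample.int(length(parts))]
      out[i] <- paste(parts, collapse = ".")
    }
  })
  out
}

## Strip tetrahedral and double-bond stereo annotations from a SMILES string.
## Used for stereo-agnostic product comparison.
strip_stereo <- function(s) {
  s <- gsub("@", "", s, fixed = TRUE)
  s <- gsub("[/\\\\]", "-", s)
  s
}
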