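# Interface labels from solvation-energy records or inter-chain geometry.

#' Parse PISA-style per-interface residue records
#'
#' Accepts either the PISA interface XML dialect (elements
#' `interface > residue` carrying chain, residue number and solvation-energy
#' gain) or a simple TSV with columns `chain`, `resno`, `interface_id`,
#' `delta` (kcal/M).  One record is returned per (residue, interface)
#' entry; a residue appearing in several interfaces yields several records.
#'
#' @param path Path to the records file.
#' @param format "auto", "xml" or "tsv".
#' @return data.frame with columns `chain`, `resno`, `ins`, `interface_id`,
#'   `delta`.
#' @export
parse_pisa_records <- function(path, format = c("auto", "xml", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("records file not found: ", path)
  if (format == "auto") {
    head1 <- readLines(path, n = 1L)
    format <- if (grepl("^\\s*<", head1)) "xml" else "tsv"
  }
  if (format == "xml") .parse_pisa_xml(path) else .parse_pisa_tsv(path)
}

.parse_pisa_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed PISA XML in ", path,
                                           ": ", conditionMessage(e)))
  ifaces <- xml2::xml_find_all(doc, ".//interface")
  rows <- list()
  for (iface in ifaces) {
    iid <- xml2::xml_text(xml2::xml_find_first(iface, "./id"))
    if (is.na(iid)) stop("interface element without <id> in ", path)
    residues <- xml2::xml_find_all(iface, ".//residue")
    for (r in residues) {
      chain <- xml2::xml_text(xml2::xml_find_first(r, "./chain"))
      resno <- xml2::xml_text(xml2::xml_find_first(r, "./seqnum"))
      ins <- xml2::xml_text(xml2::xml_find_first(r, "./inscode"))
      delta <- xml2::xml_text(xml2::xml_find_first(r, "./solvenergy"))
      if (is.na(chain) || is.na(resno) || is.na(delta))
        stop("malformed <residue> element in interface ", iid, " of ", path)
      rows[[length(rows) + 1L]] <- data.frame(
        chain = chain, resno = as.integer(resno),
        ins = ifelse(is.na(ins), "", ins),
        interface_id = as.integer(iid), delta = as.numeric(delta),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(chain = character(), resno = integer(),
                      ins = character(), interface_id = integer(),
                      delta = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

.parse_pisa_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chain", "resno", "interface_id", "delta")
  if (!all(need %in% names(df)))
    stop("PISA TSV ", path, " must have columns: ",
         paste(need, collapse = ", "))
  if (is.null(df$ins)) df$ins <- ""
  df$resno <- suppressWarnings(as.integer(df$resno))
  df$delta <- suppressWarnings(as.numeric(df$delta))
  df$interface_id <- suppressWarnings(as.integer(df$interface_id))
  if (anyNA(df$delta) || anyNA(df$resno) || anyNA(df$interface_id))
    stop("malformed numeric field in ", path, " (line ",
         which(is.na(df$delta) | is.na(df$resno))[1] + 1L, ")")
  df[, c("chain", "resno", "ins", "interface_id", "delta")]
}

.new_interface_labels <- function(labels, interfaces) {
  structure(list(labels = labels, interfaces = interfaces),
            class = "interface_labels")
}

#' @export
print.interface_labels <- function(x, ...) {
  cat("interface_labels:", sum(x$labels), "/", length(x$labels),
      "positive residues over", length(x$interfaces), "interface(s)\n")
  invisible(x)
}

#' Derive binary interface labels from solvation-energy records
#'
#' A residue is labeled 1 iff the magnitude of its solvation-energy gain
#' exceeds `eps` in at least one interface (a gain of exactly zero marks a
#' non-interfacing residue).  Per-interface residue sets are retained so
#' the Interface dataset view can re-derive labels per chain pair.
#'
#' @param records data.frame from [parse_pisa_records()].
#' @param rs [residue_set()] the records refer to.
#' @param eps Tolerance in kcal/M (default 1e-6); must be >= 0.
#' @return An `interface_labels` object: `labels` is a 0/1 vector aligned
#'   to the residues of `rs`; `interfaces` is a list of
#'   `list(id, chains, residues)` with residue indices into `rs`.
#' @export
label_from_solvation <- function(records, rs, eps = 1e-6) {
  stopifnot(eps >= 0)
  n <- n_residues(rs)
  keys <- residue_keys(rs)
  rkey <- paste0(records$chain, ":", records$resno,
                 ifelse(records$ins == "", "", records$ins))
  idx <- match(rkey, keys)
  if (anyNA(idx))
    stop("record refers to unknown residue ", rkey[which(is.na(idx))[1]])
  labels <- integer(n)
  interfaces <- list()
  for (iid in sort(unique(records$interface_id))) {
    sel <- records$interface_id == iid & abs(records$delta) > eps
    residues <- sort(unique(idx[sel]))
    labels[residues] <- 1L
    interfaces[[length(interfaces) + 1L]] <- list(
      id = iid,
      chains = sort(unique(rs$residues$chain[residues])),
      residues = residues)
  }
  .new_interface_labels(labels, interfaces)
}

#' Geometric interface labeler
#'
#' Fallback / synthetic-data labeler: a residue is labeled 1 iff its
#' C-alpha lies within `cutoff` of any C-alpha in a different chain.  One
#' interface set is produced per contacting chain pair.  Never silently
#' substituted for solvation-energy labels.
#'
#' @param rs A [residue_set()].
#' @param cutoff Inter-chain C-alpha contact radius in Angstrom
#'   (default 8).
#' @return An `interface_labels` object.
#' @export
geometric_labeler <- function(rs, cutoff = 8) {
  n <- n_residues(rs)
  chains <- unique(rs$residues$chain)
  labels <- integer(n)
  interfaces <- list()
  iid <- 0L
  if (length(chains) >= 2L) {
    d <- as.matrix(stats::dist(rs$ca))
    for (a in seq_len(length(chains) - 1L)) {
      for (b in seq.int(a + 1L, length(chains))) {
        ia <- which(rs$residues$chain == chains[a])
        ib <- which(rs$residues$chain == chains[b])
        sub <- d[ia, ib, drop = FALSE]
        hit_a <- ia[rowSums(sub <= cutoff) > 0]
        hit_b <- ib[colSums(sub <= cutoff) > 0]
        if (length(hit_a) + length(hit_b) > 0) {
          iid <- iid + 1L
          residues <- sort(c(hit_a, hit_b))
          labels[residues] <- 1L
          interfaces[[iid]] <- list(id = iid,
                                    chains = c(chains[a], chains[b]),
                                    residues = residues)
        }
      }
    }
  }
  .new_interface_labels(labels, interfaces)
}
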