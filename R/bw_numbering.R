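# Ballesteros-Weinstein numbering for class-A GPCRs.
#
# Each transmembrane helix t carries one maximally conserved anchor residue
# labelled t.50; every other helix residue is numbered by constant offset
# from that anchor (no intra-helix insertions/deletions supported).

#' Anchor table for Ballesteros-Weinstein assignment
#'
#' @param receptor_id identifier, e.g. `"MOR"`.
#' @param anchors integer vector of length 7 (names `"1"`..`"7"` optional):
#'   author residue number of the x.50 anchor of each helix.
#' @param tm_ranges data.frame with columns `tm`, `first`, `last` giving the
#'   author-numbering span of each helix. Ranges must be ordered, mutually
#'   non-overlapping, and contain their anchor.
#' @param regions optional data.frame with columns `first`, `last`, `tag`
#'   labelling non-helix segments (`N-term`, `ECL1`..`ECL3`, `ICL1`..`ICL3`,
#'   `C-term`).
#' @return an object of class `anchor_table`
#' @export
anchor_table <- function(receptor_id, anchors, tm_ranges, regions = NULL) {
  anchors <- as.integer(anchors)
  if (length(anchors) != 7) stop("exactly 7 anchors are required")
  names(anchors) <- as.character(1:7)
  stopifnot(is.data.frame(tm_ranges),
            all(c("tm", "first", "last") %in% names(tm_ranges)))
  tm_ranges <- tm_ranges[order(tm_ranges$tm), ]
  if (!identical(as.integer(tm_ranges$tm), 1:7)) {
    stop("tm_ranges must cover helices 1..7 exactly once")
  }
  if (any(tm_ranges$first > tm_ranges$last)) stop("tm range with first > last")
  for (t in 1:7) {
    if (anchors[t] < tm_ranges$first[t] || anchors[t] > tm_ranges$last[t]) {
      stop("anchor of TM", t, " (", anchors[t], ") lies outside its range")
    }
  }
  if (any(diff(tm_ranges$first) <= 0) ||
      any(tm_ranges$first[-1] <= tm_ranges$last[-7])) {
    stop("tm ranges must be ordered and non-overlapping")
  }
  structure(
    list(receptor_id = receptor_id, anchors = anchors,
         tm_ranges = tm_ranges, regions = regions),
    class = "anchor_table"
  )
}

#' Read an anchor table from YAML
#'
#' Expected layout: `receptor`, `anchors: {1: n, ..., 7: n}`,
#' `tm_ranges: [{tm, first, last}, ...]`, optional `regions`.
#' @param path YAML file
#' @export
read_anchor_table <- function(path) {
  y <- yaml::read_yaml(path)
  anchors <- unlist(y$anchors)[as.character(1:7)]
  tm <- do.call(rbind, lapply(y$tm_ranges, as.data.frame))
  regions <- if (!is.null(y$regions)) {
    do.call(rbind, lapply(y$regions, as.data.frame))
  }
  anchor_table(y$receptor, anchors, tm, regions)
}

#' Write an anchor table to YAML
#' @param x an `anchor_table`
#' @param path output file
#' @export
write_anchor_table <- function(x, path) {
  y <- list(
    receptor = x$receptor_id,
    anchors = as.list(stats::setNames(as.integer(x$anchors), names(x$anchors))),
    tm_ranges = lapply(seq_len(nrow(x$tm_ranges)), function(i) {
      as.list(x$tm_ranges[i, c("tm", "first", "last")])
    }),
    regions = if (!is.null(x$regions)) {
      lapply(seq_len(nrow(x$regions)), function(i) as.list(x$regions[i, ]))
    }
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Canonical form of a BW label: "T.PP" with two-digit position
#' @noRd
normalize_bw <- function(bw) {
  if (is.numeric(bw)) bw <- sprintf("%.2f", bw)
  parts <- strsplit(as.character(bw), ".", fixed = TRUE)[[1]]
  if (length(parts) != 2) return(as.character(bw))  # region tag, leave as-is
  sprintf("%d.%02d", as.integer(parts[1]), as.integer(parts[2]))
}

#' Assign Ballesteros-Weinstein labels to a system
#'
#' A residue r within helix t whose anchor is residue a receives position
#' `50 - (a - r)`, rendered as `"t.PP"`. Residues outside all helix ranges
#' receive the matching region tag, or `"unassigned"` with a warning when no
#' region covers them.
#'
#' @param system a `molecular_system`
#' @param anchors an `anchor_table`
#' @return the system with the `bw_label` atom column filled in
#' @export
assign_bw_numbers <- function(system, anchors) {
  stopifnot(inherits(anchors, "anchor_table"))
  at <- system$atoms
  prot <- at$kind == "protein"
  res <- at$res_number
  lab <- rep(NA_character_, nrow(at))
  unassigned <- integer(0)
  for (i in which(prot)) {
    r <- res[i]
    hit <- which(anchors$tm_ranges$first <= r & r <= anchors$tm_ranges$last)
    if (length(hit) == 1) {
      t <- as.integer(anchors$tm_ranges$tm[hit])
      pos <- as.integer(50 - (anchors$anchors[[as.character(t)]] - r))
      if (pos < 1 || pos > 99) {
        lab[i] <- "unassigned"
        unassigned <- c(unassigned, r)
      } else {
        lab[i] <- sprintf("%d.%02d", t, pos)
      }
    } else if (!is.null(anchors$regions)) {
      rhit <- which(anchors$regions$first <= r & r <= anchors$regions$last)
      if (length(rhit) >= 1) {
        lab[i] <- anchors$regions$tag[rhit[1]]
      } else {
        lab[i] <- "unassigned"
        unassigned <- c(unassigned, r)
      }
    } else {
      lab[i] <- "unassigned"
      unassigned <- c(unassigned, r)
    }
  }
  if (length(unassigned)) {
    warning("residues without BW label or region tag: ",
            paste(sort(unique(unassigned)), collapse = ", "))
  }
  system$atoms$bw_label <- lab
  system
}
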