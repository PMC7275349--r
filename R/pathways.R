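#' Signed pathway topology graph
#'
#' A pathway is a gene membership set plus a list of signed directed
#' edges. Edge relations are mapped to the signed weight beta used by
#' the perturbation model: `activation -> +1`, `inhibition -> -1`.
#' Edge endpoints must be pathway members; self-loops are permitted.
#'
#' @param database pathway database name (pathways are keyed by
#'   `(database, pathway_id)`; no cross-database deduplication).
#' @param pathway_id pathway identifier within the database.
#' @param members character vector of member gene ids (nonempty).
#' @param edges data frame with columns `source`, `target`, `relation`
#'   (or `beta`); may have zero rows.
#' @param description free-text description (GMT column 2).
#' @return A list of class `"pathway_graph"` whose `edges` element
#'   carries columns `source`, `target`, `beta`, `relation`.
#' @export
pathway_graph <- function(database, pathway_id, members,
                          edges = NULL, description = "") {
  members <- unique(as.character(members))
  if (!length(members)) stop("pathway must have members", call. = FALSE)
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        beta = numeric(), relation = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!"beta" %in% names(edges)) {
      edges$beta <- relation_beta(edges$relation)
    }
    if (!"relation" %in% names(edges)) {
      edges$relation <- ifelse(edges$beta > 0, "activation", "inhibition")
    }
    if (!all(edges$beta %in% c(-1, 1))) {
      stop("edge beta must be +1 or -1", call. = FALSE)
    }
    bad <- !(edges$source %in% members) | !(edges$target %in% members)
    if (any(bad)) {
      stop("pathway ", database, ":", pathway_id,
           " has edges with endpoints outside its membership: ",
           paste(utils::head(paste0(edges$source[bad], "->",
                                    edges$target[bad]), 5L),
                 collapse = ", "), call. = FALSE)
    }
    edges <- edges[, c("source", "target", "beta", "relation")]
    rownames(edges) <- NULL
  }
  structure(list(database = as.character(database),
                 pathway_id = as.character(pathway_id),
                 members = members, edges = edges,
                 description = as.character(description)),
            class = "pathway_graph")
}

relation_beta <- function(relation) {
  beta <- c(activation = 1, inhibition = -1)[as.character(relation)]
  if (anyNA(beta)) {
    stop("unknown relation string(s): ",
         paste(unique(relation[is.na(beta)]), collapse = ", "),
         call. = FALSE)
  }
  unname(beta)
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat("<pathway_graph>", pathway_key(x$database, x$pathway_id), "/",
      length(x$members), "genes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Key identifying a pathway across databases
#' @param database,pathway_id components of the key.
#' @return `"database|pathway_id"` string.
#' @export
pathway_key <- function(database, pathway_id) {
  paste(database, pathway_id, sep = "|")
}

#' Read pathway definitions from GMT plus a signed topology file
#'
#' The GMT file follows the standard convention: one pathway per line,
#' tab-separated as `pathway_id<TAB>description<TAB>gene1<TAB>gene2...`.
#' The topology file is a SIF-like TSV with header columns `database`,
#' `pathway_id`, `source`, `target`, `relation` where relation is
#' `activation` or `inhibition`. Edges are attached to the matching
#' `(database, pathway_id)`; an edge naming a gene outside the
#' pathway's GMT membership, or an unknown relation string, is a
#' validation error. Topology rows for other databases are ignored.
#'
#' @param gmt_path path to the GMT membership file.
#' @param topology_path path to the edge TSV, or `NULL` for
#'   topology-free (edgeless) pathways.
#' @param database database name assigned to the GMT's pathways.
#' @return A named list of [pathway_graph()] objects keyed by
#'   [pathway_key()].
#' @export
read_pathways <- function(gmt_path, topology_path = NULL,
                          database = "custom") {
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  edges_all <- NULL
  if (!is.null(topology_path)) {
    edges_all <- utils::read.delim(topology_path, stringsAsFactors = FALSE)
    need <- c("database", "pathway_id", "source", "target", "relation")
    miss <- setdiff(need, names(edges_all))
    if (length(miss)) {
      stop("topology file lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    edges_all <- edges_all[edges_all$database == database, , drop = FALSE]
  }
  out <- lapply(parts, function(p) {
    if (length(p) < 3L) {
      stop("GMT line with fewer than 3 fields: ", p[[1L]], call. = FALSE)
    }
    pid <- p[[1L]]
    e <- NULL
    if (!is.null(edges_all)) {
      e <- edges_all[edges_all$pathway_id == pid, , drop = FALSE]
      if (!nrow(e)) e <- NULL
    }
    pathway_graph(database, pid, members = p[-(1:2)], edges = e,
                  description = p[[2L]])
  })
  stats::setNames(out, vapply(out, function(g)
    pathway_key(g$database, g$pathway_id), ""))
}

#' Write pathway memberships to a GMT file
#' @param pathways list of [pathway_graph()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(pathways, function(g) {
    paste(c(g$pathway_id,
            if (nzchar(g$description)) g$description else "na",
            g$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write pathway topology edges to a TSV file
#' @param pathways list of [pathway_graph()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_topology <- function(pathways, path) {
  rows <- lapply(pathways, function(g) {
    if (!nrow(g$edges)) return(NULL)
    data.frame(database = g$database, pathway_id = g$pathway_id,
               source = g$edges$source, target = g$edges$target,
               relation = g$edges$relation, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(database = character(), pathway_id = character(),
                     source = character(), target = character(),
                     relation = character())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
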