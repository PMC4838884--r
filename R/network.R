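#' Construct a signed interaction network
#'
#' An `endo_network` is the static wiring of an endogenous molecular-cellular
#' network: named nodes grouped into functional modules, connected by signed
#' directed edges (activation or inhibition), optionally carrying per-edge
#' Hill parameters. Node order is stable and defines the indexing of state
#' vectors throughout the package.
#'
#' @param nodes data frame with columns `name` (unique, nonempty character)
#'   and `module` (label drawn from `modules`); an optional `description`
#'   column is carried along.
#' @param edges data frame with columns `source`, `target` (node names) and
#'   `sign` (`"activation"` or `"inhibition"`, abbreviations `"+"`/`"-"`
#'   accepted); optional columns `n` (Hill coefficient, >= 1) and `a`
#'   (threshold in (0,1)) give per-edge parameters, `NA` meaning "use the
#'   global default".
#' @param modules character vector of module labels, in display order.
#'   Defaults to the distinct labels appearing in `nodes`.
#' @return An object of class `endo_network` with elements `nodes`, `edges`
#'   and `modules`.
#' @seealso [parse_network()], [validate_network()], [effective_subnetwork()]
#' @examples
#' net <- endo_network(
#'   nodes = data.frame(name = c("A", "B"), module = "core"),
#'   edges = data.frame(source = c("A", "B"), target = c("B", "A"),
#'                      sign = "inhibition")
#' )
#' net
#' @export
endo_network <- function(nodes, edges = NULL, modules = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"name" %in% names(nodes)) stop("`nodes` needs a `name` column")
  if (!"module" %in% names(nodes)) nodes$module <- "default"
  nodes$name <- as.character(nodes$name)
  nodes$module <- as.character(nodes$module)
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), n = numeric(), a = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$sign <- normalize_sign(edges$sign)
    if (is.null(edges$n)) edges$n <- NA_real_
    if (is.null(edges$a)) edges$a <- NA_real_
    edges$n <- as.numeric(edges$n)
    edges$a <- as.numeric(edges$a)
    edges <- edges[, c("source", "target", "sign", "n", "a")]
  }
  if (is.null(modules)) modules <- unique(nodes$module)
  net <- structure(
    list(nodes = nodes, edges = edges, modules = as.character(modules)),
    class = "endo_network"
  )
  viol <- validate_network(net)
  if (nrow(viol) > 0) {
    stop("invalid network:\n  ", paste(viol$message, collapse = "\n  "))
  }
  net
}

normalize_sign <- function(s) {
  s <- as.character(s)
  out <- ifelse(s %in% c("+", "activation", "act", "1"), "activation",
                ifelse(s %in% c("-", "inhibition", "inh"), "inhibition", NA))
  if (anyNA(out)) stop("unknown edge sign: ", paste(unique(s[is.na(out)]), collapse = ", "))
  out
}

#' Number of nodes in a network
#' @param net an `endo_network`
#' @return integer node count
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @export
print.endo_network <- function(x, ...) {
  cat("Signed interaction network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges,", length(x$modules), "module(s)\n")
  nact <- sum(x$edges$sign == "activation")
  cat("  activation:", nact, " inhibition:", nrow(x$edges) - nact, "\n")
  cat("  modules:", paste(x$modules, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.endo_network <- function(object, ...) {
  tab <- table(factor(object$nodes$module, levels = object$modules))
  print(object)
  cat("Nodes per module:\n")
  print(tab)
  invisible(object)
}

#' Check a network against its structural invariants
#'
#' Violations are returned as data, not raised: each row names the rule
#' broken and the offending element. An empty data frame means the network
#' satisfies all invariants (unique nonempty node names, module labels drawn
#' from the declared list, edge endpoints that exist, no duplicated
#' (source, target, sign) triple, per-edge parameters in range).
#'
#' @param net an `endo_network` (or a bare list with the same fields)
#' @return data frame with columns `rule`, `element`, `message`
#' @export
validate_network <- function(net) {
  v <- list()
  add <- function(rule, element, message) {
    v[[length(v) + 1]] <<- data.frame(rule = rule, element = element,
                                      message = message, stringsAsFactors = FALSE)
  }
  nm <- net$nodes$name
  if (length(nm) == 0) add("nonempty", "<network>", "network has no nodes")
  bad <- which(!nzchar(nm))
  for (i in bad) add("node_name", sprintf("node %d", i), "empty node name")
  dup <- unique(nm[duplicated(nm)])
  for (d in dup) add("node_unique", d, sprintf("duplicated node name '%s'", d))
  off <- setdiff(unique(net$nodes$module), net$modules)
  for (m in off) add("module_label", m,
                     sprintf("module label '%s' not in declared module list", m))
  if (nrow(net$edges) > 0) {
    for (i in seq_len(nrow(net$edges))) {
      e <- net$edges[i, ]
      for (endp in c(e$source, e$target)) {
        if (!endp %in% nm)
          add("edge_endpoint", endp,
              sprintf("edge %s -> %s (%s) references undeclared node '%s'",
                      e$source, e$target, e$sign, endp))
      }
      if (!is.na(e$n) && e$n < 1)
        add("param_n", sprintf("%s->%s", e$source, e$target),
            sprintf("Hill coefficient n=%g < 1 on edge %s -> %s", e$n, e$source, e$target))
      if (!is.na(e$a) && (e$a <= 0 || e$a >= 1))
        add("param_a", sprintf("%s->%s", e$source, e$target),
            sprintf("threshold a=%g outside (0,1) on edge %s -> %s", e$a, e$source, e$target))
    }
    key <- paste(net$edges$source, net$edges$target, net$edges$sign)
    dupk <- unique(key[duplicated(key)])
    for (k in dupk) add("edge_unique", k, sprintf("duplicated edge triple (%s)", k))
  }
  if (length(v) == 0) {
    return(data.frame(rule = character(), element = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Parse a network definition document
#'
#' Two plain-text dialects are supported. The TSV dialect is line based:
#' `#module <label>` lines declare modules in order, `NODE <name> <module>`
#' lines declare nodes, and `EDGE <source> <target> <+|-> [n a]` lines
#' declare signed edges with optional per-edge Hill parameters. The JSON
#' dialect is an object with fields `modules`, `nodes` (objects with `name`,
#' `module`) and `edges` (objects with `source`, `target`, `sign` and
#' optional `n`, `a`). Node order in the document defines state-vector
#' indexing.
#'
#' @param text a character scalar (whole document) or vector of lines
#' @param dialect `"tsv"` or `"json"`; default guesses from the first
#'   non-blank character
#' @return an `endo_network`
#' @seealso [read_network()] to parse from a file path, [write_network()]
#' @export
parse_network <- function(text, dialect = c("auto", "tsv", "json")) {
  dialect <- match.arg(dialect)
  if (length(text) == 1 && grepl("\n", text)) text <- strsplit(text, "\n")[[1]]
  if (dialect == "auto") {
    first <- trimws(paste(text, collapse = "\n"))
    dialect <- if (startsWith(first, "{")) "json" else "tsv"
  }
  if (dialect == "json") return(parse_network_json(paste(text, collapse = "\n")))
  parse_network_tsv(text)
}

parse_network_tsv <- function(lines) {
  modules <- character()
  nodes <- list(); edges <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#module")) {
      lab <- trimws(sub("^#module[ \t]+", "", ln))
      if (!nzchar(lab) || lab == "#module")
        stop(sprintf("line %d: malformed module declaration", i))
      modules <- c(modules, lab)
      next
    }
    if (startsWith(ln, "#")) next  # comment
    f <- strsplit(ln, "[ \t]+")[[1]]
    if (f[1] == "NODE") {
      if (length(f) < 2) stop(sprintf("line %d: NODE needs a name", i))
      nodes[[length(nodes) + 1]] <- data.frame(
        name = f[2],
        module = if (length(f) >= 3) f[3] else "default",
        stringsAsFactors = FALSE)
    } else if (f[1] == "EDGE") {
      if (length(f) < 4 || !f[4] %in% c("+", "-"))
        stop(sprintf("line %d: malformed EDGE line (need: EDGE src tgt +|- [n a])", i))
      n <- if (length(f) >= 5) as.numeric(f[5]) else NA_real_
      a <- if (length(f) >= 6) as.numeric(f[6]) else NA_real_
      if (length(f) >= 5 && (is.na(n) || (length(f) >= 6 && is.na(a))))
        stop(sprintf("line %d: non-numeric edge parameter", i))
      edges[[length(edges) + 1]] <- data.frame(
        source = f[2], target = f[3],
        sign = if (f[4] == "+") "activation" else "inhibition",
        n = n, a = a, stringsAsFactors = FALSE)
    } else {
      stop(sprintf("line %d: unrecognized record '%s'", i, f[1]))
    }
  }
  nodes <- if (length(nodes)) do.call(rbind, nodes) else
    stop("network document declares no nodes")
  edges <- if (length(edges)) do.call(rbind, edges) else NULL
  if (length(modules) == 0) modules <- unique(nodes$module)
  check_endpoints(nodes, edges)
  endo_network(nodes, edges, modules)
}

parse_network_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt, simplifyDataFrame = TRUE)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  edges <- if (!is.null(obj$edges) && NROW(obj$edges) > 0)
    as.data.frame(obj$edges, stringsAsFactors = FALSE) else NULL
  check_endpoints(nodes, edges)
  endo_network(nodes, edges, modules = obj$modules)
}

check_endpoints <- function(nodes, edges) {
  if (is.null(edges)) return(invisible())
  missing <- setdiff(unique(c(edges$source, edges$target)), nodes$name)
  if (length(missing) > 0)
    stop("edge references undeclared node(s): ", paste(missing, collapse = ", "))
  invisible()
}

#' Read a network from a file
#' @param path file path to a TSV or JSON network definition
#' @inheritParams parse_network
#' @return an `endo_network`
#' @export
read_network <- function(path, dialect = c("auto", "tsv", "json")) {
  parse_network(readLines(path, warn = FALSE), dialect = match.arg(dialect))
}

#' Serialize a network
#'
#' Writes the TSV or JSON dialect accepted by [parse_network()]; the
#' round trip `parse_network(write_network(net))` reproduces the network,
#' including per-edge parameters, bit-exactly.
#'
#' @param net a valid `endo_network`
#' @param dialect `"tsv"` or `"json"`
#' @param path optional file path; when `NULL` the text is returned
#' @return the serialized text, invisibly when `path` is given
#' @export
write_network <- function(net, dialect = c("tsv", "json"), path = NULL) {
  dialect <- match.arg(dialect)
  viol <- validate_network(net)
  if (nrow(viol) > 0)
    stop("refusing to serialize invalid network:\n  ",
         paste(viol$message, collapse = "\n  "))
  if (dialect == "json") {
    txt <- jsonlite::toJSON(list(
      modules = net$modules,
      nodes = net$nodes[, c("name", "module")],
      edges = net$edges
    ), auto_unbox = FALSE, digits = NA, na = "null", pretty = TRUE)
    txt <- as.character(txt)
  } else {
    out <- c(
      paste("#module", net$modules),
      sprintf("NODE %s %s", net$nodes$name, net$nodes$module)
    )
    if (nrow(net$edges) > 0) {
      for (i in seq_len(nrow(net$edges))) {
        e <- net$edges[i, ]
        ln <- sprintf("EDGE %s %s %s", e$source, e$target,
                      if (e$sign == "activation") "+" else "-")
        if (!is.na(e$n)) {
          ln <- paste(ln, format(e$n, digits = 17))
          if (!is.na(e$a)) ln <- paste(ln, format(e$a, digits = 17))
        }
        out <- c(out, ln)
      }
    }
    txt <- paste(out, collapse = "\n")
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Effective sub-network of active nodes
#'
#' Restricts the wiring to the nodes that are active in a given state —
#' value strictly greater than `threshold` — keeping only the edges whose
#' endpoints are both retained. This is the sub-network responsible for
#' maintaining an attractor: applied to an attractor state it shows which
#' interactions are actually "on" in that phenotype.
#'
#' @param net an `endo_network`
#' @param state numeric state vector, one value in `[0,1]` per node
#'   (in node order)
#' @param threshold activity cut in (0,1); comparison is strict (`>`)
#' @return an `endo_network` on the active nodes (possibly empty: the
#'   node/edge frames may have zero rows)
#' @export
effective_subnetwork <- function(net, state, threshold = 0.5) {
  if (length(state) != n_nodes(net))
    stop("state dimension ", length(state), " does not match node count ", n_nodes(net))
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)")
  keep <- state > threshold
  nodes <- net$nodes[keep, , drop = FALSE]
  edges <- net$edges[net$edges$source %in% nodes$name &
                     net$edges$target %in% nodes$name, , drop = FALSE]
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, modules = net$modules),
            class = "endo_network")
}

node_index <- function(net, name) {
  i <- match(name, net$nodes$name)
  if (anyNA(i)) stop("unknown node(s): ", paste(name[is.na(i)], collapse = ", "))
  i
}
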