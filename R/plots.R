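# ggplot2 visualisations for the main result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Arc diagram of a secondary structure
#'
#' Base pairs drawn as arcs over the sequence axis; arc colour marks the
#' pair type when residues are supplied.
#'
#' @param object An `rna_structure`.
#' @param residues Optional residue string for pair typing.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rna_structure <- function(object, residues = NULL, ...) {
  pairs <- tidy(object, residues = residues)
  p <- ggplot2::ggplot()
  if (nrow(pairs)) {
    arcs <- purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
      i <- pairs$i[r]; j <- pairs$j[r]
      t <- seq(0, pi, length.out = 40)
      tibble(x = (i + j) / 2 + (j - i) / 2 * cos(t),
             y = (j - i) / 2 * sin(t), grp = r,
             pair_type = if ("pair_type" %in% names(pairs)) pairs$pair_type[r]
                         else "pair")
    })
    p <- p + ggplot2::geom_path(
      data = arcs,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$grp,
                   colour = .data$pair_type),
      linewidth = 0.3)
  }
  p +
    ggplot2::geom_segment(
      data = tibble(x = 1, xend = object$length),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = 0, yend = 0)) +
    ggplot2::labs(x = "position (nt)", y = NULL, colour = NULL,
                  title = sprintf("%s: %d pairs, score %s", object$id,
                                  nrow(object$pairs), format(object$score))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Heatmap of pairwise CBC counts
#'
#' @param object A `cbc_matrix`.
#' @param which `"cbc"` (default) or `"hcbc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cbc_matrix <- function(object, which = c("cbc", "hcbc"), ...) {
  which <- match.arg(which)
  m <- object[[which]]
  long <- as_tibble(as.table(m), .name_repair = ~ c("taxon_a", "taxon_b", "n"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$taxon_a, y = .data$taxon_b,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = toupper(which)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Tree plot of an ancestral reconstruction
#'
#' Simple rectangular tree layout with node points coloured by the
#' resolved Type I / Type II state; change edges are annotated.
#'
#' @param object A resolved `fitch_asr`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fitch_asr <- function(object, ...) {
  if (is.null(object$resolved)) object <- resolve_asr(object)
  tree <- object$tree
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  # node depths (x) and tip-ordered heights (y)
  depth <- numeric(n)
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in rev(seq_len(nrow(po$edge)))) {
    v <- po$edge[e, 1]; c <- po$edge[e, 2]
    len <- if (is.null(po$edge.length)) 1 else po$edge.length[e]
    depth[c] <- depth[v] + len
  }
  y <- numeric(n)
  y[seq_len(ntip)] <- match(seq_len(ntip), po$edge[po$edge[, 2] <= ntip, 2])
  for (e in seq_len(nrow(po$edge))) {
    v <- po$edge[e, 1]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    y[v] <- mean(y[kids])
  }
  seg <- tibble(
    x = depth[tree$edge[, 1]], xend = depth[tree$edge[, 2]],
    y = y[tree$edge[, 2]], yv = y[tree$edge[, 1]])
  nodes <- tibble(node = seq_len(n), x = depth, y = y,
                  state = object$resolved,
                  label = c(tree$tip.label, rep(NA, tree$Nnode)))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$y)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$x,
                                       y = .data$yv, yend = .data$y)) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$state), size = 2.5) +
    ggplot2::geom_text(data = nodes[!is.na(nodes$label), ],
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = -0.15, size = 3) +
    ggplot2::scale_x_continuous(expand = ggplot2::expansion(mult = c(0.02, 0.2))) +
    ggplot2::labs(x = "depth", y = NULL, colour = "state",
                  title = sprintf("parsimony length %d, %d reversal(s) [%s]",
                                  object$n_steps, nrow(object$reversals),
                                  object$rule)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Type composition bar chart for a topology report
#'
#' @param report Topology report tibble from [classify_all()] or a
#'   `v4_run`'s `taxa` tibble; a `clade` column is used for faceting
#'   when present.
#' @return A ggplot object.
#' @export
plot_type_composition <- function(report) {
  if (inherits(report, "v4_run")) report <- report$taxa
  p <- ggplot2::ggplot(report, ggplot2::aes(x = .data$struct_type,
                                            fill = .data$struct_type)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "taxa", fill = NULL) +
    ggplot2::theme_minimal()
  if ("clade" %in% names(report) && !all(is.na(report$clade))) {
    p <- p + ggplot2::facet_wrap(~clade)
  }
  p
}
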