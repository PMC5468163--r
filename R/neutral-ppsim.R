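#' Simulate a genealogy under the two-population isolation coalescent
#'
#' Coalescent genealogy for `n_w` + `n_e` sampled alleles in mutational time
#' units (expected substitutions per site). Within population `i` each pair
#' of lineages coalesces at rate `2 / theta_i` (which follows from
#' `theta = 4 N mu` with branch lengths measured in expected substitutions);
#' at time `tau` before the present all surviving lineages move to the
#' ancestral population where pairs coalesce at rate `2 / theta_anc`.
#'
#' @param n_w,n_e numbers of sampled alleles per population.
#' @param theta_w,theta_e,theta_anc per-site population mutation parameters.
#' @param tau divergence time, expected substitutions per site.
#' @return list with `parent` (parent node index per node, `NA` at the root),
#'   `time` (node ages, tips at 0), `n_tips`, `tip_pop` (`"west"`/`"east"`),
#'   and `pair_time` (tip-by-tip matrix of pairwise coalescent times). Tips
#'   are nodes `1..n_tips`, west first.
#' @export
simulate_isolation_genealogy <- function(n_w, n_e, theta_w, theta_e,
                                         theta_anc, tau) {
  n <- n_w + n_e
  if (n_w < 1 || n_e < 1) stopf("need at least one sampled allele per population")
  n_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, n_nodes)
  node_time <- numeric(n_nodes)
  tmrca <- matrix(0, n, n)
  # active lineages per deme, each carrying its tip descendant set
  act <- list(west = as.list(seq_len(n_w)), east = as.list(n_w + seq_len(n_e)))
  act_id <- list(west = seq_len(n_w), east = n_w + seq_len(n_e))
  th <- c(west = theta_w, east = theta_e)
  for (d in c("west", "east")) {
    if (th[[d]] == 0 && length(act[[d]]) > 1L) {
      stopf("theta_%s = 0 with %d lineages: infinite coalescence rate",
            d, length(act[[d]]))
    }
  }
  nxt <- n + 1L
  t_now <- 0
  merge_pair <- function(deme, t) {
    k <- length(act[[deme]])
    ij <- sample.int(k, 2L)
    a <- ij[1]; b <- ij[2]
    da <- act[[deme]][[a]]; db <- act[[deme]][[b]]
    tmrca[da, db] <<- t
    tmrca[db, da] <<- t
    parent[act_id[[deme]][a]] <<- nxt
    parent[act_id[[deme]][b]] <<- nxt
    node_time[nxt] <<- t
    act[[deme]][[a]] <<- c(da, db)
    act_id[[deme]][a] <<- nxt
    act[[deme]][[b]] <<- NULL
    act_id[[deme]] <<- act_id[[deme]][-b]
    nxt <<- nxt + 1L
  }
  # isolation phase: independent coalescence within each deme until tau
  repeat {
    kw <- length(act$west); ke <- length(act$east)
    rw <- if (kw > 1) kw * (kw - 1) / theta_w else 0
    re <- if (ke > 1) ke * (ke - 1) / theta_e else 0
    rate <- rw + re
    if (rate == 0) break
    dt <- stats::rexp(1, rate)
    if (t_now + dt > tau) break
    t_now <- t_now + dt
    merge_pair(if (stats::runif(1) < rw / rate) "west" else "east", t_now)
  }
  # ancestral phase: pool remaining lineages
  act$west <- c(act$west, act$east)
  act_id$west <- c(act_id$west, act_id$east)
  act$east <- list(); act_id$east <- integer(0)
  t_now <- tau
  k <- length(act$west)
  if (k > 1 && theta_anc == 0) {
    stopf("theta_anc = 0 with %d lineages at tau: infinite coalescence rate", k)
  }
  while (k > 1) {
    t_now <- t_now + stats::rexp(1, k * (k - 1) / theta_anc)
    merge_pair("west", t_now)
    k <- k - 1L
  }
  list(parent = parent, time = node_time, n_tips = n,
       tip_pop = rep(c("west", "east"), c(n_w, n_e)),
       pair_time = tmrca)
}

# Drop JC69 mutations on a genealogy and return the tip base matrix for the
# sites actually hit. Mutation rate is 1 per site per unit branch length,
# i.e. branch lengths ARE expected substitutions per site. Each mutation
# replaces the current base by one of the other three uniformly; root bases
# uniform over {A,C,G,T}. Sites hit once take a fast path (flip the tip
# descendants of the mutated branch); multi-hit sites get a full traversal.
jc69_mutate <- function(gen, L) {
  parent <- gen$parent
  node_time <- gen$time
  has_par <- !is.na(parent)
  blen <- node_time[parent[has_par]] - node_time[has_par]
  nodes <- which(has_par)
  total_len <- sum(blen)
  n_mut <- stats::rpois(1, total_len * L)
  if (n_mut == 0) return(list(sites = matrix(integer(0), gen$n_tips, 0)))
  site <- sample.int(L, n_mut, replace = TRUE)
  br <- sample.int(length(nodes), n_mut, replace = TRUE, prob = blen)
  mtime <- node_time[nodes[br]] + stats::runif(n_mut) * blen[br]
  n_tips <- gen$n_tips
  # tip descendant sets, built bottom-up (children strictly precede parents
  # in node index order by construction)
  desc <- vector("list", length(parent))
  for (v in seq_len(n_tips)) desc[[v]] <- v
  for (v in seq_len(length(parent))) {
    p <- parent[v]
    if (!is.na(p)) desc[[p]] <- c(desc[[p]], desc[[v]])
  }
  ord <- order(node_time, decreasing = TRUE)  # root first
  hit_sites <- unique(site)
  out <- matrix(0L, n_tips, length(hit_sites))
  for (s in seq_along(hit_sites)) {
    idx <- which(site == hit_sites[s])
    root_base <- sample.int(4L, 1L)
    if (length(idx) == 1L) {
      child <- nodes[br[idx]]
      tipbase <- rep.int(root_base, n_tips)
      tipbase[intersect(desc[[child]], seq_len(n_tips))] <-
        sample((1:4)[-root_base], 1L)
      out[, s] <- tipbase
      next
    }
    base <- integer(length(parent))
    for (v in ord) {
      if (is.na(parent[v])) { base[v] <- root_base; next }
      b <- base[parent[v]]
      on_edge <- idx[nodes[br[idx]] == v]
      if (length(on_edge)) {
        for (m in on_edge[order(mtime[on_edge], decreasing = TRUE)]) {
          b <- sample((1:4)[-b], 1L)
        }
      }
      base[v] <- b
    }
    out[, s] <- base[seq_len(n_tips)]
  }
  list(sites = out)
}

#' Simulate FST and dxy for one neutral locus
#'
#' Simulates a genealogy under the isolation model, drops JC69 mutations over
#' a locus of `L` sites, picks one polymorphic biallelic site uniformly at
#' random, and computes Weir-Cockerham FST and dxy on it with the same
#' per-site operators used for empirical data. Loci with no polymorphic
#' biallelic site are reported as skipped (mirroring the ascertainment of an
#' empirical SNP panel, which is biallelic-polymorphic by construction).
#'
#' @inheritParams simulate_isolation_genealogy
#' @param L locus length in sites.
#' @param seed optional integer seed.
#' @return list: `skipped` (logical), and when not skipped `fst`, `dxy`,
#'   `count_w`, `count_e` (reference-allele counts), `n_w`, `n_e`.
#' @export
simulate_neutral_locus <- function(theta_west, theta_east, theta_anc, tau,
                                   n_w, n_e, L = 190L, seed = NULL) {
  if (n_w < 2 || n_e < 2) stopf("need n_w >= 2 and n_e >= 2 sampled alleles")
  with_seed(seed, {
    gen <- simulate_isolation_genealogy(n_w, n_e, theta_west, theta_east,
                                        theta_anc, tau)
    mut <- jc69_mutate(gen, L)
    sites <- mut$sites
    if (ncol(sites) == 0) return(list(skipped = TRUE, reason = "monomorphic"))
    n_alleles <- apply(sites, 2, function(s) length(unique(s)))
    ok <- which(n_alleles == 2L)
    if (length(ok) == 0) {
      reason <- if (any(n_alleles > 2L)) "no_biallelic" else "monomorphic"
      return(list(skipped = TRUE, reason = reason))
    }
    s <- sites[, if (length(ok) == 1L) ok else sample(ok, 1L)]
    ref <- s[1]  # designate the first sampled allele's base as reference
    is_w <- gen$tip_pop == "west"
    cw <- sum(s[is_w] == ref); ce <- sum(s[!is_w] == ref)
    list(skipped = FALSE,
         fst = wc_fst(cw, n_w, ce, n_e),
         dxy = site_dxy(cw / n_w, ce / n_e),
         count_w = cw, count_e = ce, n_w = n_w, n_e = n_e)
  })
}

#' Configuration for neutral posterior-predictive simulation
#'
#' @param loci_per_sample independent loci simulated per posterior row
#'   (default 100).
#' @param locus_length sites per locus (default 190, a typical RAD locus
#'   variant-region length).
#' @param coverage_west,coverage_east integer vectors of per-locus sampled
#'   allele counts; each simulated locus draws its sample sizes uniformly
#'   from these (a length-1 vector gives fixed counts). Emulates random
#'   sampling from the empirical distributions of locus coverage.
#' @param seed integer seed.
#' @return list of class `neutral_sim_config`.
#' @export
neutral_sim_config <- function(loci_per_sample = 100L, locus_length = 190L,
                               coverage_west = 20L, coverage_east = 20L,
                               seed = 1L) {
  stopifnot(loci_per_sample >= 1, locus_length >= 1,
            all(coverage_west >= 2), all(coverage_east >= 2))
  structure(list(loci_per_sample = as.integer(loci_per_sample),
                 locus_length = as.integer(locus_length),
                 coverage_west = as.integer(coverage_west),
                 coverage_east = as.integer(coverage_east),
                 seed = as.integer(seed)),
            class = "neutral_sim_config")
}

#' Build a null FST/dxy distribution by posterior-predictive simulation
#'
#' For every row of the posterior sample set, simulates
#' `cfg$loci_per_sample` independent neutral loci and records FST and dxy at
#' one randomly chosen polymorphic biallelic site per locus. This is the
#' neutral reference distribution against which empirical differentiation is
#' compared: empirical values in ranges the null cannot reach are poorly
#' explained by drift alone.
#'
#' @param posterior a [posterior_sample_set()].
#' @param cfg a [neutral_sim_config()].
#' @return list of class `null_distribution`: `fst`, `dxy`, `posterior_row`
#'   (provenance), `n_simulated`, `n_skipped` (named by reason).
#' @export
build_null_distribution <- function(posterior, cfg = neutral_sim_config()) {
  stopifnot(inherits(posterior, "posterior_sample_set"))
  with_seed(cfg$seed, {
    fst <- dxy <- numeric(0)
    prow <- integer(0)
    skip <- c(monomorphic = 0L, no_biallelic = 0L)
    for (r in seq_len(nrow(posterior))) {
      for (l in seq_len(cfg$loci_per_sample)) {
        n_w <- if (length(cfg$coverage_west) == 1L) cfg$coverage_west
               else sample(cfg$coverage_west, 1L)
        n_e <- if (length(cfg$coverage_east) == 1L) cfg$coverage_east
               else sample(cfg$coverage_east, 1L)
        res <- simulate_neutral_locus(posterior$theta_west[r],
                                      posterior$theta_east[r],
                                      posterior$theta_anc[r],
                                      posterior$tau[r],
                                      n_w, n_e, cfg$locus_length)
        if (res$skipped) {
          skip[res$reason] <- skip[res$reason] + 1L
        } else {
          fst <- c(fst, res$fst); dxy <- c(dxy, res$dxy)
          prow <- c(prow, r)
        }
      }
    }
    structure(list(fst = fst, dxy = dxy, posterior_row = prow,
                   n_simulated = nrow(posterior) * cfg$loci_per_sample,
                   n_skipped = skip),
              class = "null_distribution")
  })
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null_distribution: %d values from %d simulated loci (%d skipped)\n",
              length(x$fst), x$n_simulated, sum(x$n_skipped)))
  invisible(x)
}

#' Compare empirical and null distributions in bins of width 0.1
#'
#' Bins both distributions on [0, 1] (bins `[0, 0.1)`, ..., `[0.9, 1]`) and
#' runs a two-sided Fisher exact test per bin on the 2x2 table of in-bin vs
#' out-of-bin counts for empirical vs simulated values. No multiple-testing
#' correction is applied across bins; the per-bin comparisons are reported
#' raw.
#'
#' @param empirical numeric vector of empirical FST (or dxy) values in [0,1].
#' @param null a `null_distribution` or a numeric vector of simulated values.
#' @param bin_width bin width, default 0.1.
#' @param stat which null vector to use when `null` is a `null_distribution`.
#' @return data.frame: `bin_lo`, `bin_hi`, `n_empirical`, `n_simulated`,
#'   `prop_empirical`, `prop_simulated`, `p_value`.
#' @export
compare_binned <- function(empirical, null, bin_width = 0.1,
                           stat = c("fst", "dxy")) {
  stat <- match.arg(stat)
  sim <- if (inherits(null, "null_distribution")) null[[stat]] else as.numeric(null)
  empirical <- empirical[!is.na(empirical)]
  sim <- sim[!is.na(sim)]
  if (length(empirical) == 0 || length(sim) == 0) {
    stopf("both empirical and simulated vectors must be non-empty")
  }
  edges <- seq(0, 1, by = bin_width)
  if (abs(edges[length(edges)] - 1) > 1e-12) edges <- c(edges, 1)
  nb <- length(edges) - 1L
  bin_of <- function(x) pmin(findInterval(x, edges, rightmost.closed = TRUE), nb)
  be <- tabulate(bin_of(empirical), nb)
  bs <- tabulate(bin_of(sim), nb)
  p <- vapply(seq_len(nb), function(b) {
    if (be[b] == 0 && bs[b] == 0) return(1)
    tab <- matrix(c(be[b], sum(be) - be[b], bs[b], sum(bs) - bs[b]), 2)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             n_empirical = be, n_simulated = bs,
             prop_empirical = be / sum(be), prop_simulated = bs / sum(bs),
             p_value = p)
}

#' Estimated false-positive proportion in a differentiation range
#'
#' Ratio of the simulated (neutral) fraction to the empirical fraction of
#' values falling in `(range_lo, range_hi]`, capped at 1: the expected
#' proportion of neutral loci per observed locus in that range. `NA` when
#' no empirical value falls in the range.
#'
#' @param empirical numeric vector of empirical values.
#' @param null a `null_distribution` or numeric vector.
#' @param range_lo,range_hi range bounds within [0, 1], lower exclusive.
#' @param stat which null vector to use when `null` is a `null_distribution`.
#' @return a proportion in [0, 1], or `NA`.
#' @export
estimate_false_positive_rate <- function(empirical, null, range_lo, range_hi,
                                         stat = c("fst", "dxy")) {
  stat <- match.arg(stat)
  sim <- if (inherits(null, "null_distribution")) null[[stat]] else as.numeric(null)
  empirical <- empirical[!is.na(empirical)]
  in_range <- function(x) x > range_lo & x <= range_hi
  emp_frac <- mean(in_range(empirical))
  if (emp_frac == 0) return(NA_real_)
  sim_frac <- mean(in_range(sim))
  min(1, sim_frac / emp_frac)
}
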