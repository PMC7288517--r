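test_that("pairwise correlations carry correct t-based p-values", {
    set.seed(1)
    n <- 20
    x <- rnorm(n)
    m <- rbind(g1 = x, g2 = -x, g3 = rnorm(n), gconst = rep(1, n))
    colnames(m) <- paste0("s", 1:n)
    pc <- pairwiseCorrelation(m)
    expect_equal(pc$r["g1", "g1"], 1)
    expect_equal(pc$r["g1", "g2"], -1)
    expect_lt(pc$p["g1", "g2"], 1e-12)
    # zero-variance gene: r = 0, p = 1 off-diagonal
    expect_equal(pc$r["gconst", "g1"], 0)
    expect_equal(pc$p["gconst", "g3"], 1)
    # r = 0.5 at n = 20: t = 0.5 * sqrt(18 / 0.75) = 2.449, p = 0.0248
    r <- 0.5
    pRef <- 2 * pt(r * sqrt(18 / (1 - r^2)), 18, lower.tail = FALSE)
    expect_equal(pRef, 0.0248, tolerance = 2e-3)
    # agreement with cor.test on a random pair
    ct <- cor.test(m["g1", ], m["g3", ])
    expect_equal(pc$r["g1", "g3"], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pc$p["g1", "g3"], ct$p.value, tolerance = 1e-10)
    expect_error(pairwiseCorrelation(m[, 1:3]), "at least 4")
})

test_that("partial correlation matches the closed form and the
           residual-regression oracle", {
    # covariate uncorrelated with x and y: rp = r_xy
    # (constructed exactly by orthogonalization)
    set.seed(2)
    z <- rnorm(30)
    x <- rnorm(30)
    y <- rnorm(30)
    x <- residuals(lm(x ~ z))
    y <- residuals(lm(y ~ z))
    out <- partialCorrelation(x, y, z)
    expect_equal(out$rp, cor(x, y), tolerance = 1e-10)
    # closed-form spot value: r_xy = .6, r_xz = r_yz = .5 -> 0.35/0.75
    rp <- (0.6 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25))
    expect_equal(rp, 0.4666667, tolerance = 1e-6)
    # y = z exactly: degenerate, rp = 0 by convention
    expect_warning(deg <- partialCorrelation(rnorm(10), z[1:10], z[1:10]),
                   "degenerate")
    expect_equal(deg$rp, 0)
    expect_equal(deg$p, 1)
})

test_that("partial correlation equals the oracle on 1000 random triples", {
    set.seed(3)
    maxErr <- 0
    for (i in 1:1000) {
        n <- sample(6:25, 1)
        z <- rnorm(n)
        x <- rnorm(n) + runif(1, -1, 1) * z
        y <- rnorm(n) + runif(1, -1, 1) * z
        got <- partialCorrelation(x, y, z)$rp
        maxErr <- max(maxErr, abs(got - partialCorOracle(x, y, z)))
    }
    expect_lt(maxErr, 1e-10)
})

test_that("BH adjustment reproduces the hand-computed step-up", {
    expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFdr(0.013), 0.013)
    expect_equal(bhFdr(1), 1)
    expect_equal(bhFdr(numeric()), numeric())
    # hand-computed mixed case: p = (.005, .04, .03), m = 3
    # ranks (1,3,2): q3 = .04, q2 = min(.04, .045) = .04(monotone), q1=.015
    expect_equal(bhFdr(c(0.005, 0.04, 0.03)), c(0.015, 0.04, 0.04))
    set.seed(9)
    p <- runif(50)
    q <- bhFdr(p)
    expect_true(all(q >= p))            # adjustment never shrinks p
    expect_true(all(q <= 1))
    expect_error(bhFdr(c(0.5, 1.2)), "0, 1")
})

test_that("network edges require both deltas and the FDR gate", {
    set.seed(4)
    n <- 150
    genes <- sprintf("G%03d", 1:30)
    base <- matrix(rnorm(30 * n), 30, n, dimnames = list(genes, NULL))
    cm <- base
    pm <- matrix(rnorm(30 * n), 30, n, dimnames = list(genes, NULL))
    colnames(cm) <- paste0("c", 1:n)
    colnames(pm) <- paste0("p", 1:n)
    # plant one sign-flip pair: strong + in control, strong - in PD
    z1 <- rnorm(n); z2 <- rnorm(n)
    a <- sqrt(0.8 / 0.2)
    cm["G001", ] <- a * z1 + rnorm(n)
    cm["G002", ] <- a * z1 + rnorm(n)
    pm["G001", ] <- a * z2 + rnorm(n)
    pm["G002", ] <- -a * z2 + rnorm(n)
    cs <- rnorm(n)
    ps <- rnorm(n)
    net <- buildNetwork(cm, pm, cs, ps)
    ed <- networkEdges(net)
    expect_true(any(ed$gene_a == "G001" & ed$gene_b == "G002"))
    row <- ed[ed$gene_a == "G001" & ed$gene_b == "G002", ]
    # brute-force recomputation of all four coefficients for that pair
    expect_equal(row$r_control, cor(cm["G001", ], cm["G002", ]),
                 tolerance = 1e-12)
    expect_equal(row$r_pd, cor(pm["G001", ], pm["G002", ]),
                 tolerance = 1e-12)
    expect_equal(row$rp_control,
                 partialCorrelation(cm["G001", ], cm["G002", ], cs)$rp,
                 tolerance = 1e-10)
    expect_equal(row$rp_pd,
                 partialCorrelation(pm["G001", ], pm["G002", ], ps)$rp,
                 tolerance = 1e-10)
    expect_gt(row$delta_r, 0.5)
    expect_gt(row$delta_rp, 0.5)

    # identical groups: all deltas 0, no edges
    net0 <- buildNetwork(cm, cm, cs, cs)
    expect_equal(nrow(networkEdges(net0)), 0L)

    # swapping control and PD leaves the edge set unchanged
    netSwap <- buildNetwork(pm, cm, ps, cs)
    expect_equal(networkEdges(netSwap)[, c("gene_a", "gene_b")],
                 ed[, c("gene_a", "gene_b")])

    # raising the delta threshold can only remove edges
    netHi <- buildNetwork(cm, pm, cs, ps, deltaThreshold = 0.9)
    keyLo <- paste(ed$gene_a, ed$gene_b)
    edHi <- networkEdges(netHi)
    expect_true(all(paste(edHi$gene_a, edHi$gene_b) %in% keyLo))

    expect_error(buildNetwork(cm[1:5, ],
                              matrix(0, 2, n,
                                     dimnames = list(c("X1", "X2"), NULL)),
                              cs, ps), "disjoint")
})

test_that("a large delta on r alone does not create an edge", {
    # deterministic construction: r flips sign between groups, but the
    # covariate carries all of it, so the partial correlations match and
    # delta_rp ~ 0
    set.seed(5)
    n <- 100
    z <- rnorm(n)
    a <- sqrt(0.7 / 0.3)
    genes <- c("GA", "GB", "GC")
    cm <- rbind(GA = a * z + rnorm(n), GB = a * z + rnorm(n),
                GC = rnorm(n))
    pm <- rbind(GA = a * z + rnorm(n), GB = -a * z + rnorm(n),
                GC = rnorm(n))
    colnames(cm) <- paste0("c", 1:n)
    colnames(pm) <- paste0("p", 1:n)
    # aging scores equal to the shared factor: conditioning on z removes
    # the planted correlation in both groups
    net <- buildNetwork(cm, pm, z, z)
    ed <- networkEdges(net)
    expect_false(any(ed$gene_a == "GA" & ed$gene_b == "GB"))
    # while the plain delta_r for that pair is large
    expect_gt(abs(cor(cm["GA", ], cm["GB", ]) -
                  cor(pm["GA", ], pm["GB", ])), 0.5)
})

test_that("Fisher network similarity matches the enumeration oracle", {
    tab <- matrix(c(3, 1, 1, 3), 2, 2)
    expect_equal(fisher.test(tab)$p.value, 34 / 70, tolerance = 1e-12)
    expect_equal(fisherOracle(tab), 34 / 70, tolerance = 1e-12)
    set.seed(6)
    for (i in 1:25) {
        t2 <- matrix(rpois(4, 4), 2, 2)
        expect_equal(fisher.test(t2)$p.value, fisherOracle(t2),
                     tolerance = 1e-9)
    }
})

test_that("identical networks test as maximally similar, independent
           networks as unrelated", {
    mkNet <- function(edges, nodes) {
        methods::new("DifferentialNetwork", nodes = nodes,
                     edges = data.frame(gene_a = edges[, 1],
                                        gene_b = edges[, 2],
                                        delta_r = 1, delta_rp = 1,
                                        stringsAsFactors = FALSE),
                     thresholds = list(delta = 0.5, fdr = 0.05,
                                       significance_mode = "any"),
                     provenance = "test")
    }
    nodes <- sprintf("G%02d", 1:10)
    set.seed(7)
    pairs <- t(combn(nodes, 2))
    pick <- pairs[sample(nrow(pairs), 8), , drop = FALSE]
    netA <- mkNet(pick, nodes)
    sim <- networkSimilarityFisher(netA, netA)
    # enumeration oracle on the 45-pair universe with 8 shared edges
    expect_equal(sim$p,
                 fisherOracle(matrix(c(8, 0, 0, 37), 2, 2)),
                 tolerance = 1e-9)
    expect_lt(sim$p, 1e-8)

    # independent random edge sets: p approximately uniform
    ps <- vapply(1:200, function(i) {
        set.seed(100 + i)
        a <- mkNet(pairs[sample(nrow(pairs), 10), ], nodes)
        b <- mkNet(pairs[sample(nrow(pairs), 10), ], nodes)
        networkSimilarityFisher(a, b)$p
    }, 0)
    # Fisher p-values are discrete and conservative; require only that
    # they spread over (0, 1] without piling up near 0
    expect_gt(mean(ps > 0.2), 0.5)
    expect_lt(mean(ps < 0.05), 0.1)
})

test_that("the scale-free diagnostic separates hub-dominated from
           homogeneous graphs", {
    # star graph: only two degree classes -> undefined
    star <- igraph::make_star(20, mode = "undirected")
    igraph::V(star)$name <- paste0("N", 1:20)
    out <- scaleFreeCheck(star)
    expect_true(is.na(out$r))
    expect_equal(out$n_degrees, 2)

    # preferential attachment: strongly negative log-log correlation
    rs <- vapply(1:5, function(i) {
        set.seed(i)
        g <- igraph::sample_pa(1000, directed = FALSE)
        igraph::V(g)$name <- paste0("N", seq_len(1000))
        scaleFreeCheck(g)$r
    }, 0)
    expect_true(all(rs < -0.6))

    # dense Erdos-Renyi: clearly not scale-free (r near 0 or positive)
    set.seed(8)
    er <- igraph::sample_gnp(400, 0.1)
    igraph::V(er)$name <- paste0("N", seq_len(400))
    expect_gt(scaleFreeCheck(er)$r, -0.3)
})
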