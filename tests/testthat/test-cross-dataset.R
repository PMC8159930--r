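# Brute-force average-linkage recomputation straight from the distance
# matrix: clusters merge at the mean of the original pairwise distances.
upgmaOracleHeights <- function(d) {
    dm <- as.matrix(d)
    clusters <- as.list(seq_len(nrow(dm)))
    heights <- numeric(0)
    while (length(clusters) > 1) {
        best <- c(Inf, NA, NA)
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (j <= i) next
            h <- mean(dm[clusters[[i]], clusters[[j]]])
            if (h < best[1]) best <- c(h, i, j)
        }
        heights <- c(heights, best[1])
        clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
        clusters[[best[3]]] <- NULL
    }
    sort(heights)
}

test_that("set intersections enumerate every exclusive region", {
    res <- intersectGeneSets(list(X = c("a", "b", "c"), Y = c("b", "c"),
                                  Z = "c"))
    expect_identical(res$intersection, "C")
    reg <- setNames(res$regions$count, res$regions$region)
    expect_equal(unname(reg["X"]), 1)          # a
    expect_equal(unname(reg["X&Y"]), 1)        # b
    expect_equal(unname(reg["X&Y&Z"]), 1)      # c
    expect_equal(sum(res$regions$count), 3)    # |union|

    same <- intersectGeneSets(list(P = letters[1:4], Q = letters[1:4]))
    expect_equal(sum(same$regions$count[same$regions$region != "P&Q"]), 0)
    expect_length(same$intersection, 4)

    disj <- intersectGeneSets(list(P = "a", Q = "b"))
    expect_length(disj$intersection, 0)
    expect_error(intersectGeneSets(list(P = "a")), "parameter error")
})

test_that("region counts always sum to the union size", {
    set.seed(8)
    for (i in 1:5) {
        m <- sample(2:5, 1)
        sets <- setNames(lapply(seq_len(m), function(j)
            sample(letters, sample(3:15, 1))), paste0("D", seq_len(m)))
        res <- intersectGeneSets(sets)
        expect_equal(sum(res$regions$count),
                     length(unique(toupper(unlist(sets)))))
    }
})

test_that("UPGMA merges forced configurations correctly", {
    # d(A,B) = 1, d(A,C) = d(B,C) = 4: merge (A,B) at 1, then C at 4
    # coordinates chosen so the Euclidean distances are exactly 1, 4, 4
    m <- rbind(A = c(0, 0), B = c(1, 0), C = c(0.5, sqrt(16 - 0.25)))
    cl <- upgmaCluster(m)
    expect_equal(cl$height, c(1, 4), tolerance = 1e-9)
    expect_equal(cl$merge[1, ], c(-1, -2))
    # duplicated rows merge at height 0
    dup <- rbind(A = c(1, 1), B = c(1, 1), C = c(5, 5))
    expect_equal(upgmaCluster(dup)$height[1], 0)
    expect_error(upgmaCluster(m[1, , drop = FALSE]), "parameter error")
})

test_that("UPGMA heights match a brute-force recomputation", {
    set.seed(23)
    for (i in 1:8) {
        m <- matrix(rnorm(6 * 4), 6, dimnames = list(paste0("I", 1:6), NULL))
        cl <- upgmaCluster(m)
        expect_equal(sort(cl$height),
                     upgmaOracleHeights(dist(m[order(rownames(m)), ])),
                     tolerance = 1e-9)
        expect_true(!is.unsorted(cl$height))
    }
    # permutation invariance of the heights
    m <- matrix(rnorm(24), 6, dimnames = list(paste0("I", 1:6), NULL))
    cl1 <- upgmaCluster(m)
    cl2 <- upgmaCluster(m[sample(6), , drop = FALSE])
    expect_equal(sort(cl1$height), sort(cl2$height), tolerance = 1e-12)
    expect_identical(cl1$labels[cl1$order], cl2$labels[cl2$order])
})

test_that("flow profiles are zero-imputed and cluster across contexts", {
    res <- runContrast(16)
    fpm <- flowProfileMatrix(list(A = res$solA, B = res$solB))
    expect_true(all(is.finite(fpm)))
    onlyB <- setdiff(names(nodeThroughput(res$solB)),
                     names(nodeThroughput(res$solA)))
    expect_true(all(fpm[onlyB, "A"] == 0))
    cl <- upgmaCluster(fpm, axis = "rows")
    expect_length(cl$height, nrow(fpm) - 1)
    ph <- ape::read.tree(text = cl$newick)
    expect_setequal(ph$tip.label, rownames(fpm))
    clc <- upgmaCluster(fpm, axis = "columns")
    expect_length(clc$height, 1)
})
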