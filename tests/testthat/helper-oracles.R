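# Independent oracles used across the suite. Deliberately naive
# implementations: brute force, enumeration, closed forms.

# BH step-up by explicit min-over-tail
bruteBH <- function(p) {
    m <- length(p)
    r <- rank(p, ties.method = "first")
    vapply(seq_len(m), function(i) {
        tail <- p[r >= r[i]]
        tailRank <- r[r >= r[i]]
        min(1, min(m * tail / tailRank))
    }, numeric(1))
}

# adjusted Rand index from the pair-counting formula
adjustedRand <- function(a, b) {
    tab <- table(a, b)
    sumij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2))
    bj <- sum(choose(colSums(tab), 2))
    n <- length(a)
    expect <- ai * bj / choose(n, 2)
    (sumij - expect) / ((ai + bj) / 2 - expect)
}

# upper-tail hypergeometric p by full enumeration over overlaps
bruteHyper <- function(x, K, N, n) {
    js <- x:min(K, n)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# upper-tail binomial p by direct summation
bruteBinomTail <- function(x, n, p) {
    if (x <= 0) return(1)
    sum(choose(n, x:n) * p^(x:n) * (1 - p)^(n - (x:n)))
}

# --- exhaustive DFS path enumeration on a mixed graph (no igraph) -------

# adjacency under mixed semantics: ppi both ways, reg forward only
oracleAdjacency <- function(net, undirectedAll = FALSE) {
    e <- networkEdges(net)
    adj <- setNames(vector("list", length(networkNodes(net))),
                    networkNodes(net))
    for (i in seq_len(nrow(e))) {
        adj[[e$from[i]]] <- c(adj[[e$from[i]]], e$to[i])
        if (undirectedAll || e$type[i] == "ppi")
            adj[[e$to[i]]] <- c(adj[[e$to[i]]], e$from[i])
    }
    lapply(adj, unique)
}

# all simple paths s -> t by depth-first search, then keep the shortest
oracleShortestPaths <- function(net, s, t, undirectedAll = FALSE) {
    adj <- oracleAdjacency(net, undirectedAll)
    found <- list()
    recurse <- function(path) {
        last <- path[length(path)]
        if (last == t) {
            found[[length(found) + 1L]] <<- path
            return(invisible())
        }
        for (nb in adj[[last]])
            if (!nb %in% path) recurse(c(path, nb))
    }
    recurse(s)
    if (length(found) == 0L) return(list())
    lens <- vapply(found, length, integer(1))
    found[lens == min(lens)]
}

oracleAllPairPaths <- function(net, sources, sinks, undirectedAll = FALSE) {
    paths <- list()
    for (s in sources) for (t in sinks)
        paths <- c(paths, oracleShortestPaths(net, s, t, undirectedAll))
    key <- vapply(paths, function(p)
        paste(p[1], p[length(p)], paste(p, collapse = ">"), sep = "\r"),
        character(1))
    paths[order(key)]
}

oracleScores <- function(net, sources, sinks, undirectedAll = FALSE) {
    paths <- oracleAllPairPaths(net, sources, sinks, undirectedAll)
    nodes <- networkNodes(net)
    cnt <- setNames(numeric(length(nodes)), nodes)
    lenSum <- cnt
    for (p in paths) {
        interior <- setdiff(p[-c(1, length(p))], c(sources, sinks))
        cnt[interior] <- cnt[interior] + 1
        lenSum[interior] <- lenSum[interior] + (length(p) - 1L)
    }
    score <- ifelse(cnt > 0, cnt / (lenSum / cnt), 0)
    score[nodes %in% c(sources, sinks)] <- NA_real_
    score
}

# random small mixed graph with 1-2 sources and 1-2 sinks
randomMixedGraph <- function(seed) {
    set.seed(seed)
    n <- sample(5:12, 1)
    nodes <- sprintf("V%02d", seq_len(n))
    pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < 0.35
    e <- data.frame(from = nodes[pairs[keep, 1]],
                    type = sample(c("ppi", "reg"), sum(keep),
                                  replace = TRUE, prob = c(0.7, 0.3)),
                    to = nodes[pairs[keep, 2]],
                    stringsAsFactors = FALSE)
    flip <- runif(nrow(e)) < 0.5        # randomize reg orientation
    tmp <- e$from[flip]
    e$from[flip] <- e$to[flip]
    e$to[flip] <- tmp
    roleNodes <- sample(nodes, sample(2:4, 1))
    nSrc <- sample(seq_len(length(roleNodes) - 1L), 1)
    InteractionNetwork(e, sources = roleNodes[seq_len(nSrc)],
                       sinks = roleNodes[-seq_len(nSrc)], nodes = nodes)
}

# two well-separated planted profile groups for clustering tests
twoGroupProfiles <- function(seed, n = 60, p = 5, sep = 4, sd = 0.5) {
    set.seed(seed)
    mu1 <- c(rep(-sep / 2, ceiling(p / 2)), rep(sep / 2, floor(p / 2)))
    x <- rbind(matrix(rnorm(n / 2 * p, 0, sd), n / 2, p, byrow = TRUE) +
                   matrix(mu1, n / 2, p, byrow = TRUE),
               matrix(rnorm(n / 2 * p, 0, sd), n / 2, p, byrow = TRUE) -
                   matrix(mu1, n / 2, p, byrow = TRUE))
    rownames(x) <- sprintf("g%03d", seq_len(n))
    list(x = x, labels = rep(1:2, each = n / 2))
}

# small ready-made experiment shared by several tests
smallSimulation <- function(seed = 42L, nProbes = 800L, ...) {
    spec <- syntheticExpressionSpec(nProbes = nProbes, pluriOnGenes = 40L,
                                    fibroOffGenes = 40L, rngSeed = seed,
                                    ...)
    simulateExpression(spec)
}
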