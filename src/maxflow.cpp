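#include <Rcpp.h>
#include <climits>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Unit-capacity max flow on the residual matrix `cap` (row-major V x V),
// shortest augmenting paths (BFS). An undirected edge {u,v} of capacity 1 is
// represented as two opposite arcs of capacity 1; residual updates follow the
// standard cancellation rule, so the value equals the number of pairwise
// edge-disjoint undirected paths. `cap` is consumed (left in residual state).
static int max_flow_residual(std::vector<int>& cap, int V, int s, int t,
                             std::vector<int>& parent, std::vector<int>& queue) {
    int flow = 0;
    for (;;) {
        std::fill(parent.begin(), parent.end(), -1);
        parent[s] = s;
        int head = 0, tail = 0;
        queue[tail++] = s;
        while (head < tail && parent[t] == -1) {
            const int u = queue[head++];
            const int* row = &cap[(size_t)u * V];
            for (int v = 0; v < V; ++v) {
                if (row[v] > 0 && parent[v] == -1) {
                    parent[v] = u;
                    queue[tail++] = v;
                }
            }
        }
        if (parent[t] == -1) break;
        int aug = INT_MAX;
        for (int v = t; v != s; v = parent[v])
            aug = std::min(aug, cap[(size_t)parent[v] * V + v]);
        for (int v = t; v != s; v = parent[v]) {
            cap[(size_t)parent[v] * V + v] -= aug;
            cap[(size_t)v * V + parent[v]] += aug;
        }
        flow += aug;
    }
    return flow;
}

static std::vector<int> as_capacity(const IntegerMatrix& adj) {
    const int V = adj.nrow();
    std::vector<int> cap((size_t)V * V);
    for (int i = 0; i < V; ++i)
        for (int j = 0; j < V; ++j)
            cap[(size_t)i * V + j] = adj(i, j);
    return cap;
}

// [[Rcpp::export(name = ".cpp_max_flow")]]
int cpp_max_flow(IntegerMatrix adj, int source, int sink) {
    const int V = adj.nrow();
    std::vector<int> cap = as_capacity(adj);
    std::vector<int> parent(V), queue(V);
    return max_flow_residual(cap, V, source, sink, parent, queue);
}

// All-pairs max flow of an undirected unit-capacity graph via Gusfield's
// flow-equivalent tree: V-1 max-flow computations; the pairwise value is the
// minimum tree-edge weight on the path between the two nodes.
// [[Rcpp::export(name = ".cpp_all_pairs_flow")]]
IntegerMatrix cpp_all_pairs_flow(IntegerMatrix adj) {
    const int V = adj.nrow();
    IntegerMatrix out(V, V);
    if (V < 2) return out;

    const std::vector<int> base = as_capacity(adj);
    std::vector<int> cap((size_t)V * V);
    std::vector<int> parent(V), queue(V);
    std::vector<int> tree_parent(V, 0), tree_weight(V, 0);
    std::vector<char> side(V);

    for (int i = 1; i < V; ++i) {
        cap = base;
        const int t = tree_parent[i];
        tree_weight[i] = max_flow_residual(cap, V, i, t, parent, queue);
        // nodes reachable from i in the residual graph form i's side of a min cut
        std::fill(side.begin(), side.end(), 0);
        side[i] = 1;
        int head = 0, tail = 0;
        queue[tail++] = i;
        while (head < tail) {
            const int u = queue[head++];
            const int* row = &cap[(size_t)u * V];
            for (int v = 0; v < V; ++v) {
                if (row[v] > 0 && !side[v]) {
                    side[v] = 1;
                    queue[tail++] = v;
                }
            }
        }
        for (int j = i + 1; j < V; ++j)
            if (tree_parent[j] == t && side[j]) tree_parent[j] = i;
    }

    // adjacency list of the flow-equivalent tree
    std::vector<std::vector<std::pair<int, int> > > tree(V);
    for (int i = 1; i < V; ++i) {
        tree[i].push_back(std::make_pair(tree_parent[i], tree_weight[i]));
        tree[tree_parent[i]].push_back(std::make_pair(i, tree_weight[i]));
    }

    // propagate min edge weight from every root by DFS
    std::vector<int> stack(V), minw(V);
    std::vector<char> seen(V);
    for (int r = 0; r < V; ++r) {
        std::fill(seen.begin(), seen.end(), 0);
        seen[r] = 1;
        int top = 0;
        stack[top++] = r;
        minw[r] = INT_MAX;
        while (top > 0) {
            const int u = stack[--top];
            for (size_t e = 0; e < tree[u].size(); ++e) {
                const int v = tree[u][e].first;
                if (seen[v]) continue;
                seen[v] = 1;
                minw[v] = std::min(minw[u], tree[u][e].second);
                out(r, v) = minw[v];
                stack[top++] = v;
            }
        }
    }
    return out;
}
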