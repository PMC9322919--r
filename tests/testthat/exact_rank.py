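"""Exact-arithmetic oracle for single-input controllability ranks.

Reads a JSON file describing weighted digraphs whose weights are dyadic
rationals num/denom, assembles the controllability matrix
C = (b, Ab, ..., A^(N-1) b) for every node in exact integer arithmetic
(scaling A by denom rescales the columns of C and leaves the rank
unchanged), and writes the per-node ranks as JSON.

Usage: python exact_rank.py graphs.json ranks.json
"""
import json
import sys

from sympy import Matrix


def node_ranks(n, edges):
    # a_ij = weight of edge j -> i, scaled to integers
    A = [[0] * n for _ in range(n)]
    for src, tgt, num in edges:
        A[tgt - 1][src - 1] = int(num)
    A = Matrix(A)
    ranks = []
    for v in range(n):
        b = Matrix([0] * n)
        b[v] = 1
        cols = [b]
        for _ in range(n - 1):
            cols.append(A * cols[-1])
        C = Matrix.hstack(*cols)
        ranks.append(C.rank())
    return ranks


def main():
    with open(sys.argv[1]) as fh:
        graphs = json.load(fh)
    out = [node_ranks(g["n"], g.get("edges", [])) for g in graphs]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
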