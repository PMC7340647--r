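// Hot kernels of the D3Q19 solver: collision, streaming with fused
// boundary handling, outlet density pin and moment evaluation.
//
// Distributions are stored as a 19 x n_cells matrix (column = cell) so a
// cell's populations are contiguous.  All index matrices are 1-based as
// built on the R side; 0 marks "not applicable".
//
// Link types (per unknown direction i at cell x, upstream y = x + c_opp(i)):
//   0 fluid     : plain streaming pull from y
//   1 wall      : Bouzidi linear interpolated bounce-back (q in (0,1]),
//                 optional moving-wall momentum term
//   2 inlet     : half-way velocity bounce-back against the inflow profile
//   3 outlet    : first-order extrapolation from the interior neighbor

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// Collide all cells in place: f <- f + C (feq - f).  Returns c(max |u|,
// min rho) for the Mach/divergence guard.  cmat is the 19 x 3 stencil,
// w the weights; C is the dense 19x19 collision operator (Omega * I for
// BGK).  `work` is a caller-owned 19 x n scratch matrix holding the
// non-equilibrium part; the 19x19 x n contraction runs as one BLAS dgemm.
// [[Rcpp::export]]
NumericVector lbm_collide_cpp(NumericMatrix f, const NumericMatrix C,
                              const IntegerMatrix cmat,
                              const NumericVector w,
                              Nullable<NumericMatrix> work = R_NilValue) {
  const int n = f.ncol();
  NumericMatrix wk = work.isNull() ? NumericMatrix(19, n)
                                   : NumericMatrix(work);
  double cx[19], cy[19], cz[19], wl[19];
  for (int i = 0; i < 19; ++i) {
    cx[i] = cmat(i, 0); cy[i] = cmat(i, 1); cz[i] = cmat(i, 2);
    wl[i] = w[i];
  }
  double maxu2 = 0.0, minrho = R_PosInf;
  double* fp = REAL(f);
  double* wkp = REAL(wk);
  for (int x = 0; x < n; ++x) {
    double* fc = fp + (R_xlen_t)19 * x;
    double* wc = wkp + (R_xlen_t)19 * x;
    double rho = 0.0, jx = 0.0, jy = 0.0, jz = 0.0;
    for (int i = 0; i < 19; ++i) {
      const double v = fc[i];
      rho += v; jx += v * cx[i]; jy += v * cy[i]; jz += v * cz[i];
    }
    if (rho < minrho) minrho = rho;
    const double ux = jx / rho, uy = jy / rho, uz = jz / rho;
    const double u2 = ux * ux + uy * uy + uz * uz;
    if (u2 > maxu2) maxu2 = u2;
    for (int i = 0; i < 19; ++i) {
      const double cu = cx[i] * ux + cy[i] * uy + cz[i] * uz;
      const double feq = rho * wl[i] *
        (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * u2);
      wc[i] = feq - fc[i];
    }
  }
  // f += C * fneq for all cells at once
  const int m19 = 19;
  const double one = 1.0;
  F77_CALL(dgemm)("N", "N", &m19, &n, &m19, &one, REAL(C), &m19,
                  wkp, &m19, &one, fp, &m19 FCONE FCONE);
  return NumericVector::create(std::sqrt(maxu2), minrho);
}

// Stream post-collision fsrc into fdst with fused boundary handling.
// pull(i,x): 1-based source cell for types 0 and 3.
// qm(i,x):   Bouzidi q of the wall link opp(i) from x (type 1).
// aux(i,x):  1-based index of the fluid neighbor x + c_i (second
//            interpolation node for q < 1/2); 0 -> fall back to half-way.
// icoef(i,x): moving-wall / inflow momentum term at full target strength,
//            scaled by ramp (in [0,1]) at run time.
// [[Rcpp::export]]
void lbm_stream_cpp(const NumericMatrix fsrc, NumericMatrix fdst,
                    const IntegerMatrix pull, const IntegerMatrix ltype,
                    const NumericMatrix qm, const IntegerMatrix aux,
                    const NumericMatrix icoef, const double ramp,
                    const IntegerVector opp) {
  const int n = fsrc.ncol();
  const double* fs = REAL(fsrc);
  double* fd = REAL(fdst);
  const int* pl = INTEGER(pull);
  const int* lt = INTEGER(ltype);
  const int* ax = INTEGER(aux);
  const double* qv = REAL(qm);
  const double* ic = REAL(icoef);
  int oppl[19];
  for (int i = 0; i < 19; ++i) oppl[i] = opp[i] - 1;
  for (int x = 0; x < n; ++x) {
    const R_xlen_t base = (R_xlen_t)19 * x;
    for (int i = 0; i < 19; ++i) {
      const R_xlen_t k = base + i;
      const int t = lt[k];
      double val;
      if (t == 0 || t == 3) {
        val = fs[(R_xlen_t)19 * (pl[k] - 1) + i];
      } else if (t == 1) {
        const int j = oppl[i];
        const double q = qv[k];
        if (q < 0.5) {
          const int ff = ax[k];
          if (ff > 0)
            val = 2.0 * q * fs[base + j] +
                  (1.0 - 2.0 * q) * fs[(R_xlen_t)19 * (ff - 1) + j];
          else
            val = fs[base + j];           // isolated cell: half-way fallback
        } else {
          const double inv2q = 0.5 / q;
          val = inv2q * fs[base + j] + (1.0 - inv2q) * fs[base + i];
        }
        val += ic[k] * ramp;
      } else {                            // t == 2, inlet half-way
        val = fs[base + oppl[i]] + ic[k] * ramp;
      }
      fd[k] = val;
    }
  }
}

// Pin the density of the listed cells (1-based) to rho0.
// mode 0: momentum-preserving shift f_i += w_i (rho0 - rho).
// mode 1: replace by the equilibrium at (rho0, u): discards the
//   non-equilibrium part in the outlet layer, which damps the pressure
//   and shear disturbances a truncated jet otherwise reflects.
// [[Rcpp::export]]
void lbm_density_pin_cpp(NumericMatrix f, const IntegerVector cells,
                         const NumericVector w, const double rho0,
                         const IntegerMatrix cmat, const int mode) {
  double* fp = REAL(f);
  double wl[19], cx[19], cy[19], cz[19];
  for (int i = 0; i < 19; ++i) {
    wl[i] = w[i];
    cx[i] = cmat(i, 0); cy[i] = cmat(i, 1); cz[i] = cmat(i, 2);
  }
  for (int s = 0; s < cells.size(); ++s) {
    double* fc = fp + (R_xlen_t)19 * (cells[s] - 1);
    double rho = 0.0;
    for (int i = 0; i < 19; ++i) rho += fc[i];
    if (mode == 0) {
      const double d = rho0 - rho;
      for (int i = 0; i < 19; ++i) fc[i] += wl[i] * d;
    } else {
      double jx = 0.0, jy = 0.0, jz = 0.0;
      for (int i = 0; i < 19; ++i) {
        jx += fc[i] * cx[i]; jy += fc[i] * cy[i]; jz += fc[i] * cz[i];
      }
      const double ux = jx / rho, uy = jy / rho, uz = jz / rho;
      const double u2 = ux * ux + uy * uy + uz * uz;
      for (int i = 0; i < 19; ++i) {
        const double cu = cx[i] * ux + cy[i] * uy + cz[i] * uz;
        fc[i] = rho0 * wl[i] * (1.0 + 3.0 * cu + 4.5 * cu * cu - 1.5 * u2);
      }
    }
  }
}

// Density and velocity of every cell: returns 4 x n (rho, ux, uy, uz).
// [[Rcpp::export]]
NumericMatrix lbm_macro_cpp(const NumericMatrix f, const IntegerMatrix cmat) {
  const int n = f.ncol();
  NumericMatrix out(4, n);
  double cx[19], cy[19], cz[19];
  for (int i = 0; i < 19; ++i) {
    cx[i] = cmat(i, 0); cy[i] = cmat(i, 1); cz[i] = cmat(i, 2);
  }
  const double* fp = REAL(f);
  double* op = REAL(out);
  for (int x = 0; x < n; ++x) {
    const double* fc = fp + (R_xlen_t)19 * x;
    double rho = 0.0, jx = 0.0, jy = 0.0, jz = 0.0;
    for (int i = 0; i < 19; ++i) {
      const double v = fc[i];
      rho += v; jx += v * cx[i]; jy += v * cy[i]; jz += v * cz[i];
    }
    op[4 * x] = rho;
    op[4 * x + 1] = jx / rho;
    op[4 * x + 2] = jy / rho;
    op[4 * x + 3] = jz / rho;
  }
  return out;
}
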