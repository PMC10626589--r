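#!/usr/bin/env python
"""Independent reference evaluation of the PW91k (LC94) kinetic and PBE
exchange-correlation energy densities, written directly from the published
parameterizations. Used by the test suite as a double-entry check against
the package's R implementation.

stdin:  lines of "rho sigma"
stdout: lines of "tau_pw91k exc_pbe" (energy densities, a.u.)
"""
import sys
import numpy as np

C_TF = 0.3 * (3 * np.pi**2) ** (2.0 / 3.0)


def pw91k(rho, sigma):
    s = np.sqrt(sigma) / (2 * (3 * np.pi**2) ** (1.0 / 3.0) * rho ** (4.0 / 3.0))
    A1, A2, A3, A4, A, B1 = 0.093907, 0.26608, 0.0809615, 100.0, 76.32, 0.000057767
    t = A1 * s * np.arcsinh(A * s)
    num = 1 + t + (A2 - A3 * np.exp(-A4 * s**2)) * s**2
    den = 1 + t + B1 * s**4
    return C_TF * rho ** (5.0 / 3.0) * num / den


def pw92_ec(rs):
    A, a1 = 0.0310907, 0.21370
    b1, b2, b3, b4 = 7.5957, 3.5876, 1.6382, 0.49294
    q0 = -2 * A * (1 + a1 * rs)
    q1 = 2 * A * (b1 * np.sqrt(rs) + b2 * rs + b3 * rs**1.5 + b4 * rs**2)
    return q0 * np.log(1 + 1 / q1)


def pbe_xc(rho, sigma):
    kappa, mu = 0.804, 0.2195149727645171
    kf = (3 * np.pi**2 * rho) ** (1.0 / 3.0)
    ex_lda = -(3.0 / 4.0) * (3.0 / np.pi) ** (1.0 / 3.0) * rho ** (1.0 / 3.0)
    s2 = sigma / (4 * kf**2 * rho**2)
    fx = 1 + kappa - kappa / (1 + mu * s2 / kappa)
    ex = ex_lda * fx * rho

    beta = 0.06672455060314922
    gamma = (1 - np.log(2.0)) / np.pi**2
    rs = (3.0 / (4 * np.pi * rho)) ** (1.0 / 3.0)
    ec = pw92_ec(rs)
    ks = np.sqrt(4 * kf / np.pi)
    t2 = sigma / (4 * ks**2 * rho**2)
    Aden = np.expm1(-ec / gamma)
    Afac = (beta / gamma) / Aden
    num = 1 + Afac * t2
    den = 1 + Afac * t2 + Afac**2 * t2**2
    H = gamma * np.log(1 + (beta / gamma) * t2 * num / den)
    return ex + (ec + H) * rho


def main():
    data = np.loadtxt(sys.stdin, ndmin=2)
    rho, sigma = data[:, 0], data[:, 1]
    tau = pw91k(rho, sigma)
    exc = pbe_xc(rho, sigma)
    for a, b in zip(tau, exc):
        sys.stdout.write(f"{a:.16e} {b:.16e}\n")


if __name__ == "__main__":
    main()
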