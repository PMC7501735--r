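/* Minimal HDF5 bindings for the coilqa container.
 *
 * The container layout is fixed by the package (see ?write_container):
 * double-precision datasets at group paths such as /raw/kspace_re, plus
 * scalar/vector attributes on the root group.  Only what that layout
 * needs is implemented: double datasets of arbitrary rank, and root
 * attributes of type string, double vector or integer vector.
 *
 * Dataset dims are passed/returned in HDF5 (row-major) order; the R
 * wrappers handle the column-major transpose.
 */

#include <hdf5.h>
#include <string.h>
#include <stdlib.h>
#include <R.h>
#include <Rinternals.h>

static void quiet_errors(void) {
    H5Eset_auto2(H5E_DEFAULT, NULL, NULL);
}

/* ---------------------------------------------------------------- write */

SEXP C_h5_write(SEXP path, SEXP ds_names, SEXP ds_dims, SEXP ds_data,
                SEXP at_names, SEXP at_vals)
{
    quiet_errors();
    const char *fname = CHAR(STRING_ELT(path, 0));
    hid_t file = H5Fcreate(fname, H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
    if (file < 0) error("cannot create HDF5 file '%s'", fname);

    hid_t lcpl = H5Pcreate(H5P_LINK_CREATE);
    H5Pset_create_intermediate_group(lcpl, 1);

    int nds = LENGTH(ds_names);
    for (int i = 0; i < nds; i++) {
        const char *nm = CHAR(STRING_ELT(ds_names, i));
        SEXP dimv = VECTOR_ELT(ds_dims, i);
        SEXP dat  = VECTOR_ELT(ds_data, i);
        int rank = LENGTH(dimv);
        hsize_t hdims[8];
        R_xlen_t nelem = 1;
        for (int d = 0; d < rank; d++) {
            hdims[d] = (hsize_t) INTEGER(dimv)[d];
            nelem *= INTEGER(dimv)[d];
        }
        if (nelem != XLENGTH(dat)) {
            H5Pclose(lcpl); H5Fclose(file);
            error("dataset '%s': dims inconsistent with data length", nm);
        }
        hid_t space = H5Screate_simple(rank, hdims, NULL);
        hid_t dset = H5Dcreate2(file, nm, H5T_IEEE_F64LE, space,
                                lcpl, H5P_DEFAULT, H5P_DEFAULT);
        if (dset < 0) {
            H5Sclose(space); H5Pclose(lcpl); H5Fclose(file);
            error("cannot create dataset '%s'", nm);
        }
        H5Dwrite(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                 REAL(dat));
        H5Dclose(dset);
        H5Sclose(space);
    }
    H5Pclose(lcpl);

    int nat = LENGTH(at_names);
    for (int i = 0; i < nat; i++) {
        const char *nm = CHAR(STRING_ELT(at_names, i));
        SEXP v = VECTOR_ELT(at_vals, i);
        hid_t space, atype, attr;
        if (TYPEOF(v) == STRSXP) {
            const char *s = CHAR(STRING_ELT(v, 0));
            atype = H5Tcopy(H5T_C_S1);
            H5Tset_size(atype, strlen(s) + 1);
            space = H5Screate(H5S_SCALAR);
            attr = H5Acreate2(file, nm, atype, space, H5P_DEFAULT, H5P_DEFAULT);
            H5Awrite(attr, atype, s);
            H5Tclose(atype);
        } else if (TYPEOF(v) == INTSXP) {
            hsize_t n = (hsize_t) LENGTH(v);
            space = (n == 1) ? H5Screate(H5S_SCALAR)
                             : H5Screate_simple(1, &n, NULL);
            attr = H5Acreate2(file, nm, H5T_STD_I32LE, space,
                              H5P_DEFAULT, H5P_DEFAULT);
            H5Awrite(attr, H5T_NATIVE_INT, INTEGER(v));
        } else {
            hsize_t n = (hsize_t) LENGTH(v);
            space = (n == 1) ? H5Screate(H5S_SCALAR)
                             : H5Screate_simple(1, &n, NULL);
            attr = H5Acreate2(file, nm, H5T_IEEE_F64LE, space,
                              H5P_DEFAULT, H5P_DEFAULT);
            H5Awrite(attr, H5T_NATIVE_DOUBLE, REAL(v));
        }
        H5Aclose(attr);
        H5Sclose(space);
    }

    H5Fclose(file);
    return R_NilValue;
}

/* ----------------------------------------------------------------- read */

typedef struct {
    char **names;
    int n, cap;
} name_list;

static herr_t visit_cb(hid_t obj, const char *name, const H5O_info_t *info,
                       void *op_data)
{
    (void) obj;
    name_list *nl = (name_list *) op_data;
    if (info->type == H5O_TYPE_DATASET) {
        if (nl->n == nl->cap) {
            nl->cap = nl->cap ? 2 * nl->cap : 16;
            nl->names = realloc(nl->names, nl->cap * sizeof(char *));
        }
        nl->names[nl->n++] = strdup(name);
    }
    return 0;
}

static void free_names(name_list *nl)
{
    for (int i = 0; i < nl->n; i++) free(nl->names[i]);
    free(nl->names);
}

SEXP C_h5_read(SEXP path)
{
    quiet_errors();
    const char *fname = CHAR(STRING_ELT(path, 0));
    hid_t file = H5Fopen(fname, H5F_ACC_RDONLY, H5P_DEFAULT);
    if (file < 0) error("cannot open HDF5 file '%s'", fname);

    /* datasets */
    name_list nl = { NULL, 0, 0 };
#if H5_VERSION_GE(1, 12, 0)
    H5Ovisit3(file, H5_INDEX_NAME, H5_ITER_NATIVE, visit_cb, &nl,
              H5O_INFO_BASIC);
#else
    H5Ovisit(file, H5_INDEX_NAME, H5_ITER_NATIVE, visit_cb, &nl);
#endif

    SEXP ds_names = PROTECT(allocVector(STRSXP, nl.n));
    SEXP ds_dims  = PROTECT(allocVector(VECSXP, nl.n));
    SEXP ds_data  = PROTECT(allocVector(VECSXP, nl.n));
    for (int i = 0; i < nl.n; i++) {
        SET_STRING_ELT(ds_names, i, mkChar(nl.names[i]));
        hid_t dset = H5Dopen2(file, nl.names[i], H5P_DEFAULT);
        hid_t space = H5Dget_space(dset);
        int rank = H5Sget_simple_extent_ndims(space);
        hsize_t hdims[8];
        H5Sget_simple_extent_dims(space, hdims, NULL);
        SEXP dimv = PROTECT(allocVector(INTSXP, rank));
        R_xlen_t nelem = 1;
        for (int d = 0; d < rank; d++) {
            INTEGER(dimv)[d] = (int) hdims[d];
            nelem *= (R_xlen_t) hdims[d];
        }
        SEXP dat = PROTECT(allocVector(REALSXP, nelem));
        H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                REAL(dat));
        SET_VECTOR_ELT(ds_dims, i, dimv);
        SET_VECTOR_ELT(ds_data, i, dat);
        UNPROTECT(2);
        H5Sclose(space);
        H5Dclose(dset);
    }
    free_names(&nl);

    /* root attributes */
    hid_t root = H5Gopen2(file, "/", H5P_DEFAULT);
    int nat = (int) H5Aget_num_attrs(root);
    SEXP at_names = PROTECT(allocVector(STRSXP, nat));
    SEXP at_vals  = PROTECT(allocVector(VECSXP, nat));
    for (int i = 0; i < nat; i++) {
        hid_t attr = H5Aopen_by_idx(root, ".", H5_INDEX_NAME, H5_ITER_NATIVE,
                                    (hsize_t) i, H5P_DEFAULT, H5P_DEFAULT);
        char nm[256];
        H5Aget_name(attr, sizeof nm, nm);
        SET_STRING_ELT(at_names, i, mkChar(nm));
        hid_t atype = H5Aget_type(attr);
        hid_t aspace = H5Aget_space(attr);
        hssize_t n = H5Sget_simple_extent_npoints(aspace);
        H5T_class_t cls = H5Tget_class(atype);
        if (cls == H5T_STRING) {
            size_t sz = H5Tget_size(atype);
            char *buf = calloc(sz + 1, 1);
            hid_t mtype = H5Tcopy(H5T_C_S1);
            H5Tset_size(mtype, sz + 1);
            H5Aread(attr, mtype, buf);
            SET_VECTOR_ELT(at_vals, i, mkString(buf));
            free(buf);
            H5Tclose(mtype);
        } else if (cls == H5T_INTEGER) {
            SEXP v = PROTECT(allocVector(INTSXP, (R_xlen_t) n));
            H5Aread(attr, H5T_NATIVE_INT, INTEGER(v));
            SET_VECTOR_ELT(at_vals, i, v);
            UNPROTECT(1);
        } else {
            SEXP v = PROTECT(allocVector(REALSXP, (R_xlen_t) n));
            H5Aread(attr, H5T_NATIVE_DOUBLE, REAL(v));
            SET_VECTOR_ELT(at_vals, i, v);
            UNPROTECT(1);
        }
        H5Tclose(atype);
        H5Sclose(aspace);
        H5Aclose(attr);
    }
    H5Gclose(root);
    H5Fclose(file);

    SEXP out = PROTECT(allocVector(VECSXP, 5));
    SET_VECTOR_ELT(out, 0, ds_names);
    SET_VECTOR_ELT(out, 1, ds_dims);
    SET_VECTOR_ELT(out, 2, ds_data);
    SET_VECTOR_ELT(out, 3, at_names);
    SET_VECTOR_ELT(out, 4, at_vals);
    SEXP nms = PROTECT(allocVector(STRSXP, 5));
    SET_STRING_ELT(nms, 0, mkChar("ds_names"));
    SET_STRING_ELT(nms, 1, mkChar("ds_dims"));
    SET_STRING_ELT(nms, 2, mkChar("ds_data"));
    SET_STRING_ELT(nms, 3, mkChar("at_names"));
    SET_STRING_ELT(nms, 4, mkChar("at_vals"));
    setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(7);
    return out;
}

/* ---------------------------------------------------------- registration */

#include <R_ext/Rdynload.h>

static const R_CallMethodDef call_entries[] = {
    {"C_h5_write", (DL_FUNC) &C_h5_write, 6},
    {"C_h5_read",  (DL_FUNC) &C_h5_read,  1},
    {NULL, NULL, 0}
};

void R_init_coilqa(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
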