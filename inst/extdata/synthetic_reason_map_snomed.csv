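source_code,intermediate_code
910000007,401
910000014,402
910000021,403
910000028,404
910000035,405
910000042,406
910000049,407
910000056,408
910000063,409
910000070,410
910000077,411
910000084,412
910000091,413
910000098,414
910000105,415
910000112,416
910000119,417
910000126,418
910000133,419
910000140,420
910000147,421
910000154,422
910000161,423
910000168,424
910000175,425
910000182,426
910000189,427
910000196,428
910000203,429
910000210,430
910000217,431
910000224,432
910000231,433
910000238,434
910000245,435
910000252,436
910000259,437
910000266,438
910000273,439
910000280,440
910000287,441
910000294,442
910000301,443
910000308,444
910000315,445
910000322,446
910000329,447
910000336,448
910000343,449
910000350,450
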