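pattern,category
MEDICARE|\bMCR\b,Medicare
MEDICAID|\bMCD\b,Medicaid
SELF.?PAY|UNINSURED|NO INSURANCE,Self-pay
BCBS|BLUE CROSS|BLUE SHIELD|BLUECROSS|ANTHEM,Blue Cross/Blue Shield
COMMERCIAL|PPO|HMO|EPO|\bPOS\b|AETNA|CIGNA|UNITED|\bUHC\b|HUMANA|TRICARE|KAISER,Commercial (non-BC/BS)
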