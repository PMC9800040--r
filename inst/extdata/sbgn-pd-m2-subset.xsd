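<?xml version="1.0" encoding="UTF-8"?>
<!-- Structural schema for the SBGN-ML Process Description (milestone 2)
     dialect emitted by the sbgnyed package. Authored for this package: a
     converter-owned structural subset, not the official libSBGN schema. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           xmlns:sbgn="http://sbgn.org/libsbgn/0.2"
           targetNamespace="http://sbgn.org/libsbgn/0.2"
           elementFormDefault="qualified">

  <xs:element name="sbgn">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="map" type="sbgn:mapType"/>
      </xs:sequence>
    </xs:complexType>
  </xs:element>

  <xs:complexType name="mapType">
    <xs:sequence>
      <xs:element name="extension" type="sbgn:extensionType" minOccurs="0"/>
      <xs:element name="glyph" type="sbgn:glyphType" minOccurs="0"
                  maxOccurs="unbounded"/>
      <xs:element name="arc" type="sbgn:arcType" minOccurs="0"
                  maxOccurs="unbounded"/>
    </xs:sequence>
    <xs:attribute name="language" type="xs:string"/>
    <xs:attribute name="id" type="xs:string"/>
  </xs:complexType>

  <xs:complexType name="extensionType">
    <xs:sequence>
      <xs:any processContents="skip" minOccurs="0" maxOccurs="unbounded"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="labelType">
    <xs:attribute name="text" type="xs:string" use="required"/>
  </xs:complexType>

  <xs:complexType name="bboxType">
    <xs:attribute name="x" type="xs:decimal" use="required"/>
    <xs:attribute name="y" type="xs:decimal" use="required"/>
    <xs:attribute name="w" type="xs:decimal" use="required"/>
    <xs:attribute name="h" type="xs:decimal" use="required"/>
  </xs:complexType>

  <xs:complexType name="stateType">
    <xs:attribute name="value" type="xs:string"/>
    <xs:attribute name="variable" type="xs:string"/>
  </xs:complexType>

  <xs:complexType name="cloneType">
    <xs:sequence>
      <xs:element name="label" type="sbgn:labelType" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="portType">
    <xs:attribute name="id" type="xs:ID" use="required"/>
    <xs:attribute name="x" type="xs:decimal" use="required"/>
    <xs:attribute name="y" type="xs:decimal" use="required"/>
  </xs:complexType>

  <xs:complexType name="glyphType">
    <xs:sequence>
      <xs:element name="extension" type="sbgn:extensionType" minOccurs="0"/>
      <xs:element name="label" type="sbgn:labelType" minOccurs="0"/>
      <xs:element name="state" type="sbgn:stateType" minOccurs="0"/>
      <xs:element name="clone" type="sbgn:cloneType" minOccurs="0"/>
      <xs:element name="bbox" type="sbgn:bboxType"/>
      <xs:element name="glyph" type="sbgn:glyphType" minOccurs="0"
                  maxOccurs="unbounded"/>
      <xs:element name="port" type="sbgn:portType" minOccurs="0"
                  maxOccurs="unbounded"/>
    </xs:sequence>
    <xs:attribute name="class" type="xs:string" use="required"/>
    <xs:attribute name="id" type="xs:ID" use="required"/>
    <xs:attribute name="compartmentRef" type="xs:IDREF"/>
    <xs:attribute name="orientation" type="xs:string"/>
  </xs:complexType>

  <xs:complexType name="pointType">
    <xs:attribute name="x" type="xs:decimal" use="required"/>
    <xs:attribute name="y" type="xs:decimal" use="required"/>
  </xs:complexType>

  <xs:complexType name="arcType">
    <xs:sequence>
      <xs:element name="extension" type="sbgn:extensionType" minOccurs="0"/>
      <xs:element name="start" type="sbgn:pointType"/>
      <xs:element name="next" type="sbgn:pointType" minOccurs="0"
                  maxOccurs="unbounded"/>
      <xs:element name="end" type="sbgn:pointType"/>
    </xs:sequence>
    <xs:attribute name="class" type="xs:string" use="required"/>
    <xs:attribute name="id" type="xs:ID" use="required"/>
    <xs:attribute name="source" type="xs:IDREF" use="required"/>
    <xs:attribute name="target" type="xs:IDREF" use="required"/>
  </xs:complexType>

</xs:schema>
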